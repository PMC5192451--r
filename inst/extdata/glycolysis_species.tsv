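name	dfg0_kj_mol	charge	n_hydrogen	reactant	compartment	reference_group
3-Phospho-glyceroyl phosphate (4-)	-2356.14	-4	4	3-Phospho-glyceroyl phosphate	c	NA
3-Phospho-glyceroyl phosphate (3-)	-2401.58	-3	5	3-Phospho-glyceroyl phosphate	c	NA
2-Phospho-glycerate (3-)	-1496.38	-3	4	2-Phospho-glycerate	c	NA
2-Phospho-glycerate (2-)	-1539.99	-2	5	2-Phospho-glycerate	c	NA
3-Phospho-glycerate (3-)	-1502.54	-3	4	3-Phospho-glycerate	c	NA
3-Phospho-glycerate (2-)	-1545.52	-2	5	3-Phospho-glycerate	c	NA
ADP (3-)	-1906.13	-3	12	ADP	c	NA
ADP (2-)	-1947.1	-2	13	ADP	c	NA
ADP (1-)	-1971.98	-1	14	ADP	c	NA
ATP (4-)	-2768.1	-4	12	ATP	c	NA
ATP (3-)	-2811.48	-3	13	ATP	c	NA
ATP (2-)	-2838.18	-2	14	ATP	c	NA
Glycerone phosphate (2-)	-1296.26	-2	5	Glycerone phosphate	c	NA
Glycerone phosphate (1-)	-1328.8	-1	6	Glycerone phosphate	c	NA
Fructose 6-phosphate (2-)	-1760.8	-2	11	Fructose 6-phosphate	c	NA
Fructose 6-phosphate (1-)	-1796.6	-1	12	Fructose 6-phosphate	c	NA
Fructose 1,6-bisphosphate (4-)	-2601.4	-4	10	Fructose 1,6-bisphosphate	c	NA
Fructose 1,6-bisphosphate (3-)	-2639.36	-3	11	Fructose 1,6-bisphosphate	c	NA
Fructose 1,6-bisphosphate (2-)	-2673.89	-2	12	Fructose 1,6-bisphosphate	c	NA
Glyceraldehyde 3-phosphate (2-)	-1288.6	-2	5	Glyceraldehyde 3-phosphate	c	NA
Glyceraldehyde 3-phosphate (1-)	-1321.14	-1	6	Glyceraldehyde 3-phosphate	c	NA
Glucose	-915.9	0	12	Glucose	c	NA
Glucose 6-phosphate (2-)	-1763.94	-2	11	Glucose 6-phosphate	c	NA
Glucose 6-phosphate (1-)	-1800.59	-1	12	Glucose 6-phosphate	c	NA
H2O	-237.19	0	2	H2O	c	NA
NAD	0	-1	26	NAD	c	nad_redox
NADH	22.65	-2	27	NADH	c	nad_redox
Phosphoenolpyruvate (3-)	-1263.65	-3	2	Phosphoenolpyruvate	c	NA
Phosphoenolpyruvate (2-)	-1303.61	-2	3	Phosphoenolpyruvate	c	NA
Pi (2-)	-1096.1	-2	1	Pi	c	NA
Pi (1-)	-1137.3	-1	2	Pi	c	NA
Pyruvate	-472.27	-1	3	Pyruvate	c	NA
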