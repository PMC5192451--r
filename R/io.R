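#' Parse a reaction equation string
#'
#' Parses equations of the form `"Glucose + ATP = Glucose 6-phosphate + ADP"`.
#' The arrow encodes directionality: `=` reversible, `->` forward only,
#' `<-` backward only. Terms are separated by `+` with surrounding spaces;
#' a leading numeric token is a stoichiometric coefficient (`"2 A + B = C"`).
#' Proton tokens (`H+`) are stripped with a warning; reactant names may
#' contain spaces, digits and commas.
#'
#' @param text Equation string.
#' @param id Reaction id (defaults to the equation text).
#' @param is_transport Passed through to [reaction()].
#' @return A [reaction()] object.
#' @examples
#' parse_reaction_equation("Glucose + ATP = Glucose 6-phosphate + ADP", id = "HEX1")
#' parse_reaction_equation("A -> B")
#' @export
parse_reaction_equation <- function(text, id = text, is_transport = FALSE) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(trimws(text)))
  text <- trimws(text)
  arrow <- if (grepl("<->", text, fixed = TRUE)) "<->"
  else if (grepl("->", text, fixed = TRUE)) "->"
  else if (grepl("<-", text, fixed = TRUE)) "<-"
  else if (grepl("=", text, fixed = TRUE)) "="
  else stop("no reaction arrow ('=', '->', '<-') found in: ", text)
  directionality <- switch(arrow,
    "=" = "reversible", "<->" = "reversible",
    "->" = "forward_only", "<-" = "backward_only")
  sides <- strsplit(text, arrow, fixed = TRUE)[[1L]]
  if (length(sides) == 1L) stop("empty reaction side in: ", text)
  if (length(sides) != 2L) stop("malformed equation (need one arrow): ", text)

  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) stop("empty reaction side in: ", text)
    terms <- trimws(strsplit(side, "\\s+\\+\\s+")[[1L]])
    out <- numeric(0)
    for (term in terms) {
      if (!nzchar(term)) stop("empty term in equation: ", text)
      m <- regmatches(term, regexec("^([0-9]+\\.?[0-9]*)\\s+(.+)$", term))[[1L]]
      if (length(m) == 3L) {
        coef <- as.numeric(m[2L]); name <- m[3L]
      } else {
        coef <- 1; name <- term
      }
      out <- c(out, stats::setNames(sign * coef, name))
    }
    out
  }
  stoich <- c(parse_side(sides[1L], -1), parse_side(sides[2L], +1))
  reaction(id, stoich, directionality = directionality, is_transport = is_transport)
}

#' Format a reaction as a canonical equation string
#'
#' Inverse of [parse_reaction_equation()]: substrates (negative
#' coefficients) on the left, products on the right, unit coefficients
#' omitted, arrow chosen from the directionality.
#'
#' @param reaction A [reaction()] object.
#' @return A single string.
#' @export
format_reaction_equation <- function(reaction) {
  stopifnot(inherits(reaction, "thermo_reaction"))
  s <- reaction$stoichiometry
  fmt <- function(coef, name) {
    if (abs(coef - 1) < 1e-12) name else paste(format(coef), name)
  }
  lhs <- mapply(fmt, -s[s < 0], names(s)[s < 0])
  rhs <- mapply(fmt, s[s > 0], names(s)[s > 0])
  arrow <- switch(reaction$directionality,
    reversible = "=", forward_only = "->", backward_only = "<-")
  paste(paste(lhs, collapse = " + "), arrow, paste(rhs, collapse = " + "))
}

# tolerant numeric parser: accepts Unicode minus (as used in published
# tables) alongside ASCII hyphen-minus
parse_numeric <- function(x) {
  suppressWarnings(as.numeric(gsub("−", "-", trimws(x))))
}

#' Read a species table into pseudoisomer-grouped reactants
#'
#' Reads a TSV with columns `name`, `dfg0_kj_mol`, `charge`, `n_hydrogen`,
#' `reactant`, `compartment` (one row per protonation state; rows sharing
#' `reactant` form a pseudoisomer group) and an optional `reference_group`
#' column tagging relative reference conventions. Unicode minus signs in
#' numeric fields are accepted. Validation errors name the offending row.
#'
#' @param path Path to the TSV file.
#' @return A named list of [reactant()] objects, in file order.
#' @examples
#' tsv <- system.file("extdata", "glycolysis_species.tsv", package = "thermonet")
#' length(read_species_table(tsv))
#' @export
read_species_table <- function(path) {
  if (!file.exists(path)) stop("species table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  required <- c("name", "dfg0_kj_mol", "charge", "n_hydrogen", "reactant", "compartment")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("species table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(tab) == 0L) return(stats::setNames(list(), character(0)))
  num <- function(col) {
    v <- parse_numeric(tab[[col]])
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("non-numeric '", col, "' in species table row ", bad[1L],
           " ('", tab$name[bad[1L]], "')")
    }
    v
  }
  dfg0 <- num("dfg0_kj_mol"); charge <- num("charge"); nh <- num("n_hydrogen")
  refg <- if ("reference_group" %in% names(tab)) tab$reference_group else NA_character_
  sp <- lapply(seq_len(nrow(tab)), function(i) {
    if (!nzchar(trimws(tab$name[i]))) stop("empty species name in row ", i)
    species(tab$name[i], dfg0[i], charge[i], nh[i],
            reference_group = if (length(refg) > 1L) refg[i] else refg)
  })
  groups <- split(seq_len(nrow(tab)), factor(tab$reactant, levels = unique(tab$reactant)))
  out <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    comp <- unique(tab$compartment[idx])
    if (length(comp) > 1L) {
      stop("reactant '", g, "' spans multiple compartments (rows ",
           paste(idx, collapse = ", "), ")")
    }
    reactant(g, sp[idx], compartment = comp)
  })
  stats::setNames(out, names(groups))
}

#' Write reactants back to a species table TSV
#'
#' Writes the layout accepted by [read_species_table()]; reading the result
#' reproduces the input groups.
#'
#' @param reactants Named list of [reactant()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_species_table <- function(reactants, path) {
  rows <- do.call(rbind, lapply(reactants, function(r) {
    do.call(rbind, lapply(r$species, function(s) {
      data.frame(name = s$name, dfg0_kj_mol = s$dfg0, charge = s$charge,
                 n_hydrogen = s$n_hydrogen, reactant = r$name,
                 compartment = r$compartment,
                 reference_group = s$reference_group,
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reaction model from TSV
#'
#' Reads a TSV with columns `id` and `equation` (see
#' [parse_reaction_equation()] for the equation syntax) and optional
#' transport annotation columns `n_charge` and `delta_psi_V`.
#'
#' @param path Path to the TSV file.
#' @return A named list of [reaction()] objects. Transport annotations, when
#'   present, are attached as attributes `n_charge` and `delta_psi_V`.
#' @examples
#' tsv <- system.file("extdata", "glycolysis_reactions.tsv", package = "thermonet")
#' names(read_model(tsv))
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (!all(c("id", "equation") %in% names(tab))) {
    stop("model file ", path, " needs columns 'id' and 'equation'")
  }
  has_transport <- all(c("n_charge", "delta_psi_V") %in% names(tab))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    tr <- has_transport && nzchar(trimws(tab$n_charge[i]))
    rx <- parse_reaction_equation(tab$equation[i], id = tab$id[i], is_transport = tr)
    if (tr) {
      attr(rx, "n_charge") <- parse_numeric(tab$n_charge[i])
      attr(rx, "delta_psi_V") <- parse_numeric(tab$delta_psi_V[i])
    }
    rx
  })
  stats::setNames(out, tab$id)
}

#' Write a reaction model to TSV
#'
#' @param model Named list of [reaction()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  tab <- data.frame(
    id = vapply(model, `[[`, character(1), "id"),
    equation = vapply(model, format_reaction_equation, character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read measured concentration bounds from TSV
#'
#' Reads a TSV with columns `reactant`, `c_min_M`, `c_max_M` (mol/L).
#' Bounds must satisfy `0 < c_min <= c_max`.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `reactant`, `c_min`, `c_max` and
#'   `provenance` (`"measured"`).
#' @export
read_bounds <- function(path) {
  if (!file.exists(path)) stop("bounds file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("reactant", "c_min_M", "c_max_M") %in% names(tab))) {
    stop("bounds file needs columns reactant, c_min_M, c_max_M")
  }
  c_min <- parse_numeric(tab$c_min_M); c_max <- parse_numeric(tab$c_max_M)
  bad <- which(is.na(c_min) | is.na(c_max) | c_min <= 0 | c_min > c_max)
  if (length(bad)) {
    stop("invalid bounds in row ", bad[1L], " ('", tab$reactant[bad[1L]],
         "'): need 0 < c_min <= c_max")
  }
  data.frame(reactant = tab$reactant, c_min = c_min, c_max = c_max,
             provenance = "measured", stringsAsFactors = FALSE)
}

#' Read per-compartment conditions from JSON
#'
#' Reads a JSON object keyed by compartment id, each entry holding `ph`,
#' `ionic_strength_M` and `temperature_K`, e.g.
#' `{"c": {"ph": 7, "ionic_strength_M": 0.15, "temperature_K": 298.15}}`.
#'
#' @param path Path to the JSON file.
#' @return Named list of [conditions()] objects keyed by compartment.
#' @export
read_conditions <- function(path) {
  if (!file.exists(path)) stop("conditions file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(raw) || is.null(names(raw))) {
    stop("conditions JSON must be an object keyed by compartment")
  }
  out <- lapply(names(raw), function(comp) {
    entry <- raw[[comp]]
    conditions(
      ph = entry$ph,
      ionic_strength = entry$ionic_strength_M,
      temperature = if (!is.null(entry$temperature_K)) entry$temperature_K else T_STANDARD,
      compartment = comp
    )
  })
  stats::setNames(out, names(raw))
}

#' Minimal SBML model import
#'
#' Maps an SBML file onto the package's reaction representation: species
#' references become stoichiometric coefficients and the SBML `reversible`
#' flag becomes `reversible`/`forward_only` directionality. Only core
#' elements are read (no kinetics, no units); requires the `xml2` package.
#'
#' @param path Path to an SBML (.xml) file.
#' @return A named list of [reaction()] objects.
#' @export
read_sbml_model <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("read_sbml_model() requires the 'xml2' package")
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  rxn_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rxn_nodes) == 0L) stop("no reactions found in SBML file: ", path)
  out <- lapply(rxn_nodes, function(node) {
    id <- xml2::xml_attr(node, "id")
    rev <- !identical(xml2::xml_attr(node, "reversible"), "false")
    ref <- function(xpath, sign) {
      nodes <- xml2::xml_find_all(node, xpath)
      if (length(nodes) == 0L) return(numeric(0))
      coef <- xml2::xml_attr(nodes, "stoichiometry")
      coef <- ifelse(is.na(coef), 1, as.numeric(coef))
      stats::setNames(sign * coef, xml2::xml_attr(nodes, "species"))
    }
    stoich <- c(ref(".//listOfReactants/speciesReference", -1),
                ref(".//listOfProducts/speciesReference", +1))
    reaction(id, stoich,
             directionality = if (rev) "reversible" else "forward_only")
  })
  stats::setNames(out, vapply(out, `[[`, character(1), "id"))
}
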