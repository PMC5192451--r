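#' Functional-group contribution table
#'
#' A table of additive group contributions for estimating standard Gibbs
#' energies of formation: an origin constant plus one contribution per
#' named functional group. Ring and other structural corrections are
#' ordinary named groups (e.g. `">CH- (ring)"`), not special-cased code.
#'
#' @param origin Origin constant in kJ/mol (may be 0).
#' @param contributions Named numeric vector of group contributions, kJ/mol;
#'   names must be unique.
#' @param source Label for the provenance of the table.
#' @return An object of class `group_table`.
#' @examples
#' gt <- group_table(-103.4, c("OH- (primary)" = -119.7), source = "demo")
#' @export
group_table <- function(origin, contributions, source = "unknown") {
  stopifnot(is.numeric(origin), length(origin) == 1L, is.finite(origin))
  stopifnot(is.numeric(contributions), !is.null(names(contributions)))
  if (anyDuplicated(names(contributions))) {
    stop("duplicate group names in contribution table: ",
         paste(unique(names(contributions)[duplicated(names(contributions))]),
               collapse = ", "))
  }
  structure(list(origin = origin, contributions = contributions,
                 source = as.character(source)),
            class = "group_table")
}

#' @export
print.group_table <- function(x, ...) {
  cat(sprintf("group table [%s]: origin %.1f kJ/mol, %d groups\n",
              x$source, x$origin, length(x$contributions)))
  invisible(x)
}

#' Functional-group decomposition of a compound
#'
#' Counts of named functional groups making up one compound, as produced by
#' manual decomposition of its dominant structure in aqueous solution.
#'
#' @param counts Named numeric vector of positive integer group counts.
#' @param compound Compound label.
#' @return An object of class `group_decomposition`.
#' @export
group_decomposition <- function(counts, compound = "compound") {
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  if (any(counts < 1 | counts != round(counts))) {
    stop("group counts must be positive integers (compound '", compound, "')")
  }
  structure(list(counts = counts, compound = as.character(compound)),
            class = "group_decomposition")
}

#' Estimate a standard Gibbs energy of formation from group contributions
#'
#' Evaluates the additive group-contribution model
#' \deqn{\Delta_f G^0 = P_o + \sum_j n_j P_j}
#' where `P_o` is the table's origin constant, `P_j` the contribution of
#' group `j` and `n_j` its count in the decomposition.
#'
#' @param decomposition A [group_decomposition()] (or a bare named count
#'   vector).
#' @param table A [group_table()].
#' @return Estimated standard Gibbs energy of formation in kJ/mol.
#' @examples
#' tab <- read_group_table(system.file("extdata", "groups_mavrovouniotis.tsv",
#'                                     package = "thermonet"))
#' dec <- read_decomposition(system.file("extdata", "glucose_groups.tsv",
#'                                       package = "thermonet"))
#' estimate_dfg0(dec, tab)
#' @export
estimate_dfg0 <- function(decomposition, table) {
  stopifnot(inherits(table, "group_table"))
  if (!inherits(decomposition, "group_decomposition")) {
    decomposition <- group_decomposition(decomposition)
  }
  counts <- decomposition$counts
  if (length(counts) == 0L) return(table$origin)
  unknown <- setdiff(names(counts), names(table$contributions))
  if (length(unknown)) {
    stop("group(s) not in contribution table '", table$source, "': ",
         paste(unknown, collapse = ", "))
  }
  table$origin + sum(counts * table$contributions[names(counts)])
}

#' Percent difference between an estimate and a reference value
#'
#' `100 * |estimate - reference| / |reference|`, as used to state how far a
#' group-contribution estimate lies from an experimentally observed
#' formation energy.
#'
#' @param estimate Estimated value.
#' @param reference Reference value; must be nonzero.
#' @return Percent difference (non-negative).
#' @examples
#' compare_to_reference(-898.07, -915.9)
#' @export
compare_to_reference <- function(estimate, reference) {
  stopifnot(is.numeric(estimate), is.numeric(reference))
  if (any(reference == 0)) stop("reference value must be nonzero")
  100 * abs(estimate - reference) / abs(reference)
}

#' Read a group-contribution table from TSV
#'
#' Reads columns `group`, `contribution_kj_mol`, `source`; a row with group
#' name `origin` supplies the origin constant (0 if absent). Bundled tables
#' `groups_mavrovouniotis.tsv` and `groups_jankowski.tsv` carry the glucose
#' worked-example groups.
#'
#' @param path Path to the TSV file.
#' @return A [group_table()].
#' @export
read_group_table <- function(path) {
  if (!file.exists(path)) stop("group table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("group", "contribution_kj_mol") %in% names(tab))) {
    stop("group table needs columns 'group' and 'contribution_kj_mol'")
  }
  contrib <- parse_numeric(tab$contribution_kj_mol)
  bad <- which(is.na(contrib))
  if (length(bad)) stop("non-numeric contribution in row ", bad[1L])
  src <- if ("source" %in% names(tab) && nrow(tab)) tab$source[1L] else "unknown"
  is_origin <- tab$group == "origin"
  origin <- if (any(is_origin)) contrib[which(is_origin)[1L]] else 0
  group_table(origin,
              stats::setNames(contrib[!is_origin], tab$group[!is_origin]),
              source = src)
}

#' Read a group decomposition from TSV
#'
#' Reads columns `compound`, `group`, `count` for a single compound.
#'
#' @param path Path to the TSV file.
#' @return A [group_decomposition()].
#' @export
read_decomposition <- function(path) {
  if (!file.exists(path)) stop("decomposition file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("compound", "group", "count") %in% names(tab))) {
    stop("decomposition file needs columns compound, group, count")
  }
  cnt <- parse_numeric(tab$count)
  bad <- which(is.na(cnt))
  if (length(bad)) stop("non-numeric count in row ", bad[1L])
  compound <- unique(tab$compound)
  if (length(compound) != 1L) {
    stop("decomposition file must describe exactly one compound, found: ",
         paste(compound, collapse = ", "))
  }
  group_decomposition(stats::setNames(cnt, tab$group), compound = compound)
}
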