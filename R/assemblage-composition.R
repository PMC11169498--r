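# Assemblage-composition set algebra: exclusive/shared species counts and
# percentages between survey methods, periods, and site treatments (the
# arithmetic behind Venn-diagram comparisons).

#' A labelled species set
#'
#' @param label set identifier (non-empty).
#' @param members character vector of species identifiers (deduplicated).
#' @return an object of class `species_set`.
#' @export
species_set <- function(label, members) {
  stopifnot(is.character(label), nzchar(label))
  structure(list(label = label, members = unique(as.character(members))),
            class = "species_set")
}

# round half up to a whole percent (2.5 -> 3), unlike R's round-half-even
round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Compare two species sets
#'
#' Exclusive and shared counts with the shared percentage taken of the
#' union and rounded half-up to an integer (one-decimal value also
#' reported).
#'
#' @param a,b [species_set()] objects.
#' @return `data.frame` row: `label_a`, `label_b`, `exclusive_a`,
#'   `exclusive_b`, `shared`, `union_size`, `pct_shared`,
#'   `pct_shared_1dp`.
#' @export
compare_sets <- function(a, b) {
  stopifnot(inherits(a, "species_set"), inherits(b, "species_set"))
  shared <- length(intersect(a$members, b$members))
  uni <- length(union(a$members, b$members))
  ex_a <- length(setdiff(a$members, b$members))
  ex_b <- length(setdiff(b$members, a$members))
  stopifnot(ex_a + ex_b + shared == uni)
  pct <- if (uni == 0) 0 else 100 * shared / uni
  data.frame(label_a = a$label, label_b = b$label,
             exclusive_a = ex_a, exclusive_b = ex_b, shared = shared,
             union_size = uni,
             pct_shared = round_half_up(pct),
             pct_shared_1dp = round_half_up(pct, 1),
             stringsAsFactors = FALSE)
}

#' Before/after period comparison
#'
#' [compare_sets()] plus the list of species recorded only in the later
#' period (new records).
#'
#' @param before,after [species_set()] objects.
#' @return list with `composition` (the [compare_sets()] row) and
#'   `new_records` (character vector `after` minus `before`).
#' @export
period_comparison <- function(before, after) {
  list(composition = compare_sets(before, after),
       new_records = setdiff(after$members, before$members))
}

#' Assemblage composition between site treatments
#'
#' A species belongs to a treatment class if it was detected (`Y > 0`) at
#' at least one site of that class; the two class assemblages are then
#' compared with [compare_sets()].
#'
#' @param Y species x sites detection matrix (or a `detection_data`).
#' @param site_classes character vector (or factor) of class labels, one
#'   per site, with exactly two levels.
#' @return `data.frame` row as in [compare_sets()].
#' @export
treatment_composition <- function(Y, site_classes) {
  if (inherits(Y, "detection_data")) Y <- Y$Y
  site_classes <- as.character(site_classes)
  stopifnot(length(site_classes) == ncol(Y))
  lv <- sort(unique(site_classes))
  if (length(lv) != 2) stop("site_classes must have exactly two levels")
  if (any(table(factor(site_classes, levels = lv)) == 0)) {
    stop("a treatment class has zero sites")
  }
  in_class <- function(cls) {
    rownames(Y)[rowSums(Y[, site_classes == cls, drop = FALSE] > 0) > 0]
  }
  compare_sets(species_set(lv[1], in_class(lv[1])),
               species_set(lv[2], in_class(lv[2])))
}

#' Read species lists from a two-column CSV
#'
#' Expects columns `category`, `species`; returns one [species_set()] per
#' category.
#'
#' @param path CSV file path.
#' @return named list of `species_set` objects.
#' @export
read_species_sets <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("category", "species") %in% names(df)))
  groups <- split(df$species, df$category)
  stats::setNames(lapply(names(groups), function(nm) species_set(nm, groups[[nm]])),
                  names(groups))
}
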