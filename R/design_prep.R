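# Design/response preparation: rare-species filtering, covariate
# encoding, fractional-composition conversion, descriptive summaries.

#' Drop plant species that are rare across all samples
#'
#' A plant column is dropped when its share of the total number of
#' presence observations (summed over all plant columns) is below
#' `threshold`. The share is computed on the occurrence counts, not on
#' the number of individuals.
#'
#' @param Y presence/absence [diet_matrix].
#' @param threshold proportion in \[0,1).
#' @return filtered [diet_matrix]; dropped labels in
#'   `attr(out, "dropped")`.
#' @export
filter_rare_species <- function(Y, threshold = 0.01) {
  stopifnot(inherits(Y, "diet_matrix"))
  if (attr(Y, "mode") != "presence_absence")
    stop("rare-species filtering is defined on presence/absence data")
  if (threshold < 0 || threshold >= 1) stop("threshold must lie in [0,1)")
  counts <- colSums(Y)
  total <- sum(counts)
  if (total == 0) stop("diet matrix has no presences")
  share <- counts / total
  keep <- share >= threshold | (threshold == 0)
  if (!any(keep)) stop("all plant species dropped at threshold ", threshold)
  out <- diet_matrix(unclass(Y)[, keep, drop = FALSE], "presence_absence")
  attr(out, "dropped") <- colnames(Y)[!keep]
  attr(out, "presence_share") <- share
  out
}

#' Encode the model design matrix from bat records
#'
#' Species is one-hot encoded with all levels and no global intercept, so
#' each bat species carries its own coefficient row (per-species
#' consumption indices). Sex and reproductive condition are single 0/1
#' columns (male = 1, reproductive = 1); age class contributes two
#' dummies against the adult reference. Continuous covariates (forearm,
#' mass) are standardized to mean 0, sd 1, with the constants stored for
#' inverse transform. Records with any missing modeled covariate are
#' dropped (listwise) with a message.
#'
#' @param records a [bat_records] table.
#' @param covariates which covariates enter the design.
#' @return object of class `design_matrix`: numeric matrix with
#'   attributes `centers`, `scales` (for continuous columns) and
#'   `kept_rows` (row indices of `records` used).
#' @export
encode_design <- function(records,
                          covariates = c("species", "age_class", "sex",
                                         "repro", "mass", "forearm")) {
  df <- as.data.frame(records)
  used <- intersect(c("species", "age_class", "sex", "repro", "forearm", "mass"),
                    covariates)
  if (!length(used)) stop("no covariates requested")
  complete <- stats::complete.cases(df[, used, drop = FALSE])
  if (!all(complete))
    message("dropping ", sum(!complete), " record(s) with missing covariates")
  df <- df[complete, , drop = FALSE]
  n <- nrow(df)
  cols <- list(); centers <- c(); scales <- c()
  if ("species" %in% used) {
    for (s in BAT_SPECIES) cols[[s]] <- as.numeric(df$species == s)
  }
  if ("age_class" %in% used) {
    if (length(unique(df$age_class)) < 2)
      stop("age_class has a single level; cannot encode")
    cols[["age_subadult"]] <- as.numeric(df$age_class == "subadult")
    cols[["age_juvenile"]] <- as.numeric(df$age_class == "juvenile")
  }
  if ("sex" %in% used) {
    if (length(unique(df$sex)) < 2) stop("sex has a single level; cannot encode")
    cols[["sex_male"]] <- as.numeric(df$sex == "male")
  }
  if ("repro" %in% used) {
    if (length(unique(df$repro)) < 2) stop("repro has a single level; cannot encode")
    cols[["reproductive"]] <- as.numeric(df$repro == "reproductive")
  }
  for (v in intersect(c("forearm", "mass"), used)) {
    x <- df[[v]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stop(v, " has zero variance; cannot standardize")
    m <- mean(x)
    cols[[v]] <- (x - m) / s
    centers[v] <- m; scales[v] <- s
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (n < ncol(X)) stop("fewer complete records (", n, ") than design columns (",
                        ncol(X), ")")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  structure(X, centers = centers, scales = scales,
            kept_rows = which(complete),
            class = c("design_matrix", "matrix", "array"))
}

#' Invert the standardization of a design column
#' @param X a `design_matrix`.
#' @param column a standardized continuous column name.
#' @return the raw values.
#' @export
destandardize <- function(X, column) {
  ctr <- attr(X, "centers"); scl <- attr(X, "scales")
  if (!column %in% names(ctr)) stop(column, " is not a standardized column")
  X[, column] * scl[column] + ctr[column]
}

#' Convert a presence/absence diet matrix to fractional composition
#'
#' Each row with k >= 1 presences becomes 1/k in every present column
#' (equal weighting — the information-free choice given only detection
#' data). All-absent rows stay zero and are flagged.
#'
#' @param Y presence/absence [diet_matrix].
#' @return fractional-composition [diet_matrix]; indices of all-absent
#'   rows in `attr(out, "empty_rows")`.
#' @export
to_fractional <- function(Y) {
  stopifnot(inherits(Y, "diet_matrix"))
  if (attr(Y, "mode") != "presence_absence")
    stop("input must be presence/absence")
  m <- unclass(Y)
  k <- rowSums(m)
  out <- m / ifelse(k == 0, 1, k)
  res <- diet_matrix(out, "fractional_composition")
  attr(res, "empty_rows") <- which(k == 0)
  res
}

#' Per-bat-species prevalence of a set of plants in the diet
#'
#' For each bat species, reports 100 x (number of individuals with at
#' least one presence among the filtered plant columns) / (number of
#' individuals of that species).
#'
#' @param records a [bat_records] table.
#' @param plant_filter character vector of plant labels to count
#'   (default: all columns of the occurrence matrix).
#' @return data.frame with `bat_species`, `n`, `n_with_plant`,
#'   `prevalence_pct`.
#' @export
diet_prevalence <- function(records, plant_filter = NULL) {
  occ <- attr(records, "occurrence")
  if (is.null(plant_filter)) plant_filter <- colnames(occ)
  if (!length(plant_filter)) stop("empty plant filter set")
  miss <- setdiff(plant_filter, colnames(occ))
  if (length(miss)) stop("unknown plant label(s): ", paste(miss, collapse = ", "))
  any_present <- rowSums(occ[, plant_filter, drop = FALSE]) > 0
  sp <- as.character(records$species)
  out <- do.call(rbind, lapply(unique(sp), function(s) {
    idx <- sp == s
    data.frame(bat_species = s, n = sum(idx),
               n_with_plant = sum(any_present[idx]),
               prevalence_pct = 100 * sum(any_present[idx]) / sum(idx))
  }))
  rownames(out) <- NULL
  out
}

#' Shape index: length/width ratio
#'
#' Applied to fruit and seed dimensions after averaging replicate
#' measurements (mean of measurements, then ratio of means).
#'
#' @param length,width positive dimensions (vectors recycled as usual).
#'   If `length`/`width` hold replicate measurements of one item, pass
#'   `aggregate = TRUE` to average before taking the ratio.
#' @param aggregate average the inputs first (ratio of means).
#' @return dimensionless ratio(s).
#' @export
shape_index <- function(length, width, aggregate = FALSE) {
  if (any(width <= 0)) stop("width must be strictly positive")
  if (aggregate) mean(length) / mean(width) else length / width
}
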