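#' Classify percentage diet compositions into four diet states
#'
#' A species is an insectivore if insects/invertebrates make up at least 50%
#' of its diet and each other category stays below 50%; likewise plant-eater
#' and fruit/seed-eater; everything else -- several food types each below
#' 50%, or two categories tied at exactly 50 -- is a generalist (the residual
#' category).  Percentages are used as given and are not renormalized to sum
#' to 100.
#'
#' @param pct_insect,pct_plant,pct_fruitseed Numeric vectors in `[0, 100]`,
#'   no missing values (impute first, see [impute_diet()]).
#' @return A factor with levels [diet_state_levels].
#' @export
#' @examples
#' classify_diet(60, 30, 10)   # insectivore
#' classify_diet(40, 40, 20)   # generalist
#' classify_diet(50, 50, 0)    # generalist (tie at threshold)
classify_diet <- function(pct_insect, pct_plant, pct_fruitseed) {
  p <- cbind(pct_insect, pct_plant, pct_fruitseed)
  if (anyNA(p)) stop("missing diet percentages; impute first", call. = FALSE)
  if (any(p < 0 | p > 100)) {
    stop("diet percentages must lie in [0, 100]", call. = FALSE)
  }
  hit <- p >= 50
  n_hit <- rowSums(hit)
  out <- rep(4L, nrow(p))                  # generalist
  one <- n_hit == 1L
  out[one] <- max.col(hit[one, , drop = FALSE], ties.method = "first")
  factor(diet_state_levels[out], levels = diet_state_levels)
}

validate_diet_table <- function(diet) {
  need <- c("species", "pct_insect", "pct_plant", "pct_fruitseed")
  missing <- setdiff(need, names(diet))
  if (length(missing)) {
    stop("diet table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pcts <- as.matrix(diet[need[-1L]])
  if (any(pcts < 0 | pcts > 100, na.rm = TRUE)) {
    stop("diet percentages must lie in [0, 100]", call. = FALSE)
  }
  invisible(diet)
}

#' Impute missing diet percentages
#'
#' Iterative nonparametric ensemble-regression imputation in the style of
#' missForest: missing cells are initialized at the observed column means,
#' then each incomplete column is repeatedly re-predicted by a random forest
#' trained on the other percentage columns, until the successive change in
#' imputed values rises or `max_iter` is reached.  Only the percentage
#' columns are used as predictors -- no phylogenetic information -- so the
#' imputation cannot induce a relationship between the trait and the
#' phylogeny it is later mapped on.  Observed cells are never altered;
#' imputed values are clipped to `[0, 100]`.
#'
#' @param diet A data frame with columns `species`, `pct_insect`,
#'   `pct_plant`, `pct_fruitseed` (missing cells `NA`).
#' @param seed Integer seed; the imputation is deterministic given the seed.
#' @param max_iter Iteration cap.
#' @param ntree Trees per forest.
#' @return The completed tibble, with attribute `"n_imputed"` (cells filled).
#' @export
impute_diet <- function(diet, seed = 1L, max_iter = 10L, ntree = 100L) {
  validate_diet_table(diet)
  diet <- tibble::as_tibble(diet)
  cols <- c("pct_insect", "pct_plant", "pct_fruitseed")
  miss_frac <- mean(!stats::complete.cases(diet[cols]))
  if (miss_frac >= 0.5) {
    stop("more than half of species have missing diet data (",
         round(100 * miss_frac), "%); refusing to impute", call. = FALSE)
  }
  X <- as.data.frame(diet[cols])
  na_mask <- is.na(X)
  n_imputed <- sum(na_mask)
  if (n_imputed == 0L) return(diet)
  if (any(colSums(!na_mask) == 0L)) {
    stop("a diet column is entirely missing; cannot impute", call. = FALSE)
  }
  set.seed(seed)
  for (j in seq_along(cols)) {
    X[na_mask[, j], j] <- mean(X[!na_mask[, j], j])
  }
  # columns with least missingness first, as in missForest
  ord <- order(colSums(na_mask))
  ord <- ord[colSums(na_mask)[ord] > 0L]
  prev_diff <- Inf
  prev_X <- X
  for (iter in seq_len(max_iter)) {
    for (j in ord) {
      obs <- !na_mask[, j]
      # near-constant responses are legitimate here (degenerate predictor
      # case); randomForest's regression warning is noise
      rf <- suppressWarnings(randomForest::randomForest(
        x = X[obs, -j, drop = FALSE], y = X[obs, j], ntree = ntree
      ))
      X[!obs, j] <- stats::predict(rf, X[!obs, -j, drop = FALSE])
    }
    d <- sum((X[na_mask] - prev_X[na_mask])^2) / max(sum(X[na_mask]^2), 1e-12)
    if (d >= prev_diff) {
      X <- prev_X  # keep the previous (better) imputation
      break
    }
    prev_diff <- d
    prev_X <- X
  }
  X[] <- lapply(X, function(v) pmin(100, pmax(0, v)))
  # observed cells are untouched by construction; reassert for safety
  X[!na_mask] <- as.data.frame(diet[cols])[!na_mask]
  diet[cols] <- X
  attr(diet, "n_imputed") <- n_imputed
  diet
}

#' Complete and classify a diet table
#'
#' Imputes missing percentages if any (see [impute_diet()]) and adds the
#' derived `state` column (see [classify_diet()]).
#'
#' @inheritParams impute_diet
#' @param impute Impute missing cells first?
#' @return A tibble with an added factor column `state`.
#' @export
diet_states <- function(diet, impute = TRUE, seed = 1L) {
  validate_diet_table(diet)
  diet <- tibble::as_tibble(diet)
  if (impute && anyNA(diet[c("pct_insect", "pct_plant", "pct_fruitseed")])) {
    diet <- impute_diet(diet, seed = seed)
  }
  diet$state <- classify_diet(diet$pct_insect, diet$pct_plant,
                              diet$pct_fruitseed)
  diet
}

#' Read / write a diet table as CSV
#'
#' Header `species, pct_insect, pct_plant, pct_fruitseed[, state]`; missing
#' cells empty.
#'
#' @param path File path.
#' @return `read_diet()` returns a tibble; `write_diet()` returns `path`
#'   invisibly.
#' @export
read_diet <- function(path) {
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  validate_diet_table(df)
  df
}

#' @rdname read_diet
#' @param diet A diet table.
#' @export
write_diet <- function(diet, path) {
  write.csv(diet, path, row.names = FALSE, na = "")
  invisible(path)
}
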