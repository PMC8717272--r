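#' Canonical diet-state labels
#'
#' Order used throughout when traits come from diet percentages.
#' @export
diet_state_levels <- c("insectivore", "plant-eater", "fruit/seed-eater", "generalist")

n_free_rates <- function(model, k) {
  switch(model,
    ER  = 1L,
    SYM = as.integer(k * (k - 1L) / 2L),
    ARD = as.integer(k * (k - 1L)),
    stop("unknown model: ", model, call. = FALSE)
  )
}

#' Build an Mk instantaneous rate matrix
#'
#' Constructs the k-state continuous-time Markov generator Q (rates per Ma)
#' for the ER (equal rates), SYM (symmetric rates) or ARD (all rates
#' different) parameterizations.  Off-diagonals are filled row-wise: for SYM
#' the upper triangle `(1,2), (1,3), ..., (k-1,k)` mirrored below; for ARD all
#' `k(k-1)` off-diagonal cells in row-major order.
#'
#' @param params Non-negative numeric vector of free rates; length must equal
#'   1 (ER), `k(k-1)/2` (SYM) or `k(k-1)` (ARD).
#' @param model `"ER"`, `"SYM"` or `"ARD"`.
#' @param k Number of states.
#' @param states Optional character vector of state labels (length `k`).
#' @return A `k x k` matrix of class `"rate_matrix"` with rows summing to 0
#'   and attributes `model` and `params`.
#' @export
#' @examples
#' build_rate_matrix(0.1, "ER", k = 4)
build_rate_matrix <- function(params, model = c("ER", "SYM", "ARD"), k,
                              states = NULL) {
  model <- match.arg(model)
  k <- as.integer(k)
  if (k < 2L) stop("need at least 2 states", call. = FALSE)
  nf <- n_free_rates(model, k)
  if (length(params) != nf) {
    stop(model, " with k = ", k, " requires ", nf, " rate parameter(s), got ",
         length(params), call. = FALSE)
  }
  if (anyNA(params) || any(params < 0)) {
    stop("rates must be non-negative and non-missing", call. = FALSE)
  }
  states <- states %||% paste0("s", seq_len(k))
  if (length(states) != k) stop("'states' must have length k", call. = FALSE)
  Q <- matrix(0, k, k, dimnames = list(states, states))
  if (model == "ER") {
    Q[] <- params[1L]
  } else if (model == "SYM") {
    # fill by row of the upper triangle: (1,2),(1,3),...,(k-1,k)
    idx <- which(upper.tri(Q), arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    Q[idx] <- params
    Q[idx[, c(2L, 1L), drop = FALSE]] <- params
  } else {
    off <- which(t(row(Q) != col(Q)))  # row-major off-diagonal order
    tQ <- t(Q)
    tQ[off] <- params
    Q <- t(tQ)
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  structure(Q, model = model, params = as.numeric(params),
            class = c("rate_matrix", "matrix", "array"))
}

# eigen machinery reused across edges of one likelihood evaluation
mk_eigen <- function(Q) {
  e <- eigen(unclass(Q))
  Vi <- tryCatch(solve(e$vectors), error = function(err) NULL)
  list(values = e$values, vectors = e$vectors, inv = Vi)
}

prob_from_eigen <- function(eig, t) {
  if (is.null(eig$inv)) return(NULL)
  P <- eig$vectors %*% (exp(eig$values * t) * eig$inv)
  P <- Re(P)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Transition probability matrix of an Mk model
#'
#' `P(t) = exp(Q t)`, the CTMC kernel.  Computed by eigendecomposition with a
#' scaled Taylor-series fallback for defective generators.
#'
#' @param Q A rate matrix (see [build_rate_matrix()]).
#' @param t Duration (Ma), `>= 0`.
#' @return A row-stochastic `k x k` matrix.
#' @export
transition_probabilities <- function(Q, t) {
  if (length(t) != 1L || is.na(t) || t < 0) {
    stop("'t' must be a single non-negative duration", call. = FALSE)
  }
  k <- nrow(Q)
  if (t == 0) return(diag(k))
  P <- prob_from_eigen(mk_eigen(Q), t)
  if (is.null(P) || anyNA(P)) P <- expm_series(unclass(Q) * t)
  dimnames(P) <- dimnames(Q)
  P
}

# scaling-and-squaring Taylor series matrix exponential (fallback path)
expm_series <- function(A, order = 24L) {
  s <- max(0L, ceiling(log2(max(1e-12, max(abs(A))))))
  A <- A / 2^s
  P <- diag(nrow(A))
  term <- P
  for (n in seq_len(order)) {
    term <- term %*% A / n
    P <- P + term
  }
  for (i in seq_len(s)) P <- P %*% P
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Stationary distribution of a rate matrix
#'
#' Solves `pi Q = 0` with `sum(pi) = 1`.  For ER and SYM generators this is
#' uniform.
#'
#' @param Q A rate matrix.
#' @return Numeric probability vector of length `k`.
#' @export
stationary_distribution <- function(Q) {
  k <- nrow(Q)
  A <- rbind(t(unclass(Q)), rep(1, k))
  b <- c(rep(0, k), 1)
  pi <- qr.solve(A, b)
  pi <- unname(pmax(Re(pi), 0))
  pi / sum(pi)
}

# map tip states (labels or 1-based integers) to integer codes 1..k
encode_states <- function(tip_states, states) {
  if (is.numeric(tip_states)) {
    code <- as.integer(tip_states)
    if (any(is.na(code)) || any(code < 1L) || any(code > length(states))) {
      stop("integer tip states must lie in 1..k", call. = FALSE)
    }
  } else {
    code <- match(as.character(tip_states), states)
    if (anyNA(code)) {
      bad <- unique(as.character(tip_states)[is.na(code)])
      stop("tip states not among model states: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  names(code) <- names(tip_states)
  code
}

# ordered tip state codes aligned to phy$tip.label
align_tip_states <- function(phy, tip_states, states) {
  if (is.null(names(tip_states))) {
    stop("'tip_states' must be named by tip label", call. = FALSE)
  }
  missing <- setdiff(phy$tip.label, names(tip_states))
  if (length(missing)) {
    stop("missing tip states for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  encode_states(tip_states[phy$tip.label], states)
}

# Felsenstein pruning; returns list(loglik, partials, logscale) where
# partials[v, ] are scaled conditional likelihoods at node v.
mk_prune <- function(phy, code, Q, root_prior) {
  k <- nrow(Q)
  ntip <- ape::Ntip(phy)
  nnode <- phy$Nnode
  eig <- mk_eigen(Q)
  po <- ape::reorder.phylo(phy, "postorder")
  partial <- matrix(1, ntip + nnode, k)
  partial[seq_len(ntip), ] <- 0
  partial[cbind(seq_len(ntip), code)] <- 1
  logscale <- 0
  for (i in seq_len(nrow(po$edge))) {
    par <- po$edge[i, 1L]
    chi <- po$edge[i, 2L]
    len <- po$edge.length[i]
    P <- prob_from_eigen(eig, len)
    if (is.null(P) || anyNA(P)) P <- expm_series(unclass(Q) * len)
    msg <- as.vector(P %*% partial[chi, ])
    partial[par, ] <- partial[par, ] * msg
    mx <- max(partial[par, ])
    if (mx < 1e-200) stop("numerical underflow in pruning", call. = FALSE)
    if (mx < 1e-5) {
      partial[par, ] <- partial[par, ] / mx
      logscale <- logscale + log(mx)
    }
  }
  root <- ntip + 1L
  lik <- sum(root_prior * partial[root, ])
  list(loglik = log(lik) + logscale, partial = partial, logscale = logscale,
       eig = eig)
}

resolve_root_prior <- function(root_prior, Q) {
  k <- nrow(Q)
  if (is.character(root_prior)) {
    root_prior <- match.arg(root_prior, c("stationary", "flat"))
    p <- if (root_prior == "stationary") stationary_distribution(Q) else rep(1 / k, k)
  } else {
    p <- as.numeric(root_prior)
    if (length(p) != k || any(p < 0)) {
      stop("root prior must be a length-k non-negative vector", call. = FALSE)
    }
    p <- p / sum(p)
  }
  p
}

#' Log-likelihood of tip states under an Mk model
#'
#' Felsenstein pruning over the tree: the likelihood is the sum over root
#' states of `prior * conditional likelihood`, with per-branch transition
#' probabilities `exp(Q t)`.
#'
#' @param phy A `phylo` object with branch lengths in Ma.
#' @param tip_states Named vector (names = tip labels) of state labels or
#'   1-based integer codes.
#' @param Q A rate matrix.
#' @param root_prior `"stationary"` (default), `"flat"`, or a length-k
#'   probability vector.
#' @return Log-likelihood (scalar).
#' @export
mk_loglik <- function(phy, tip_states, Q, root_prior = "stationary") {
  states <- rownames(Q) %||% paste0("s", seq_len(nrow(Q)))
  code <- align_tip_states(phy, tip_states, states)
  prior <- resolve_root_prior(root_prior, Q)
  mk_prune(phy, code, Q, prior)$loglik
}

#' Fit an Mk model by maximum likelihood
#'
#' Optimizes the free rates of an ER, SYM or ARD generator on the log-rate
#' scale with multi-start (dispersed deterministic initial values), since
#' rates span orders of magnitude and the ARD surface can be multimodal.
#'
#' @inheritParams mk_loglik
#' @param model `"ER"`, `"SYM"` or `"ARD"`.
#' @param root_prior `"stationary"` (default) or `"flat"`; the stationary
#'   prior is recomputed from the candidate Q at each evaluation.
#' @param n_starts Number of optimizer restarts (>= 5 recommended for ARD).
#' @param states Optional state labels; defaults to the sorted observed
#'   states.
#' @param reltol Convergence tolerance on the log-likelihood.
#' @return An object of class `"mk_fit"`: list with elements `Q`, `loglik`,
#'   `AIC`, `root_prior`, `model`, `k`, `states`, `convergence` (logical),
#'   `n_free`, `n_starts`.  `AIC = 2 * n_free - 2 * loglik`.
#' @seealso [compare_models()], [tidy.mk_fit()], [glance.mk_fit()]
#' @export
fit_mk <- function(phy, tip_states, model = c("SYM", "ER", "ARD"),
                   root_prior = c("stationary", "flat"), n_starts = 5L,
                   states = NULL, reltol = 1e-8) {
  model <- match.arg(model)
  root_prior <- match.arg(root_prior)
  obs <- as.character(tip_states)
  if (is.numeric(tip_states)) obs <- as.character(tip_states)
  states <- states %||% (if (is.numeric(tip_states)) {
    paste0("s", seq_len(max(as.integer(tip_states))))
  } else {
    sort(unique(obs))
  })
  k <- length(states)
  code <- align_tip_states(phy, tip_states, states)
  if (length(unique(code)) < 2L) {
    stop("only one state observed at the tips; rates are unidentifiable",
         call. = FALSE)
  }
  nf <- n_free_rates(model, k)
  # characteristic rate: one expected change per lineage depth; the search is
  # confined to [r0 * 1e-6, r0 * 100] -- beyond ~100 expected changes per
  # lineage the likelihood is flat in the rate (saturation plateau), so the
  # cap loses nothing while keeping downstream path sampling tractable
  depth <- max(ape::node.depth.edgelength(phy))
  r0 <- 1 / max(depth, .Machine$double.eps)
  lo <- log(r0) + log(1e-6)
  hi <- log(r0) + log(100)
  negll <- function(logp) {
    logp <- pmin(hi, pmax(lo, logp))
    Q <- build_rate_matrix(exp(logp), model, k, states)
    prior <- resolve_root_prior(root_prior, Q)
    ll <- tryCatch(mk_prune(phy, code, Q, prior)$loglik,
                   error = function(e) NA_real_)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  scales <- seq(-2, 2, length.out = max(2L, n_starts))
  best <- NULL
  n_ok <- 0L
  # Brent is a deterministic global search on the bounded interval, so a
  # single pass suffices for one-parameter (ER) fits
  if (nf == 1L) n_starts <- 1L
  for (s in seq_len(max(1L, n_starts))) {
    init <- rep(log(r0) + scales[((s - 1L) %% length(scales)) + 1L], nf)
    if (nf > 1L) {
      # deterministic spread across parameters to break symmetry
      init <- init + 0.3 * sin(seq_len(nf) + s)
    }
    fit <- tryCatch(
      if (nf == 1L) {
        optim(pmin(hi, pmax(lo, init)), negll, method = "Brent",
              lower = lo, upper = hi,
              control = list(reltol = reltol))
      } else {
        optim(init, negll, method = "Nelder-Mead",
              control = list(maxit = 5000L, reltol = reltol))
      },
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e10) next
    n_ok <- n_ok + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("Mk optimization failed on all ", n_starts, " starts (model ", model,
         ", k = ", k, ")", call. = FALSE)
  }
  Q <- build_rate_matrix(exp(pmin(hi, pmax(lo, best$par))), model, k, states)
  prior <- resolve_root_prior(root_prior, Q)
  ll <- -best$value
  structure(list(
    Q = Q, loglik = ll, AIC = 2 * nf - 2 * ll, root_prior = prior,
    root_prior_mode = root_prior, model = model, k = k, states = states,
    convergence = n_ok > 0L && best$convergence == 0L,
    n_free = nf, n_starts = n_starts
  ), class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk model fit (", x$model, ", k = ", x$k, " states)\n", sep = "")
  cat("  log-likelihood:", format(x$loglik, digits = 6),
      "  AIC:", format(x$AIC, digits = 6), "\n")
  cat("  root prior (", x$root_prior_mode, "): ",
      paste(format(x$root_prior, digits = 3), collapse = " "), "\n", sep = "")
  cat("  rates (per Ma):\n")
  print(round(unclass(x$Q), 5))
  invisible(x)
}

#' Tidy an Mk fit into one row per transition rate
#'
#' @param x An `mk_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `rate`.
#' @export
tidy.mk_fit <- function(x, ...) {
  Q <- unclass(x$Q)
  idx <- which(row(Q) != col(Q), arr.ind = TRUE)
  tibble::tibble(
    from = x$states[idx[, 1L]],
    to = x$states[idx[, 2L]],
    rate = Q[idx]
  ) |> dplyr::arrange(.data$from, .data$to)
}

#' One-row model summary of an Mk fit
#'
#' @param x An `mk_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `model`, `k`, `n_free`, `logLik`, `AIC`,
#'   `convergence`.
#' @export
glance.mk_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, k = x$k, n_free = x$n_free,
    logLik = x$loglik, AIC = x$AIC, convergence = x$convergence
  )
}

#' Compare SYM and ARD fits by AIC
#'
#' Chooses the model with the lower AIC; on an exact tie the model with fewer
#' free rates wins (the symmetric model, when comparing SYM against ARD).
#'
#' @param ... Two or more `mk_fit` objects fitted to the same data (same
#'   states and tree).
#' @return A tibble (one row per fit) with `model`, `n_free`, `logLik`,
#'   `AIC`, `delta_AIC`, `chosen`.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1L]]) && !inherits(fits[[1L]], "mk_fit")) {
    fits <- fits[[1L]]
  }
  if (length(fits) < 2L) stop("need at least two fits", call. = FALSE)
  if (!all(vapply(fits, inherits, TRUE, "mk_fit"))) {
    stop("all arguments must be 'mk_fit' objects", call. = FALSE)
  }
  ks <- vapply(fits, function(f) as.integer(f$k), 1L)
  if (length(unique(ks)) != 1L ||
      length(unique(vapply(fits, function(f) paste(f$states, collapse = "|"), ""))) != 1L) {
    stop("fits use different state spaces; refusing to compare", call. = FALSE)
  }
  out <- dplyr::bind_rows(lapply(fits, glance))
  out$delta_AIC <- out$AIC - min(out$AIC)
  # lower AIC wins; ties broken toward fewer parameters
  ord <- order(out$AIC, out$n_free)
  out$chosen <- seq_len(nrow(out)) == ord[1L]
  out
}
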