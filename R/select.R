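# Wavelength selection: competitive adaptive reweighted sampling (CARS)
# and the random frog algorithm, plus the shared RMSECV engine (plsr.R).
#
# CARS, per Monte Carlo run i = 1..N:
#   1. draw a random subsample of the calibration rows;
#   2. fit PLSR (latent variables chosen by CV) on the retained wavelengths;
#   3. weights w_j = |b_j| / sum|b| from the autoscaled-X coefficients;
#   4. enforced elimination: keep the top ceil(r_i * p) wavelengths, where
#      r_i follows the exponentially decreasing function (EDF) with
#      r_1 = 1 and r_N = 2/p;
#   5. adaptive reweighted sampling over the survivors;
#   6. score the run's subset by RMSECV on the full calibration block.
# The subset with the lowest RMSECV across runs (ties: earliest run) wins.

#' Parameters for CARS wavelength selection
#'
#' Defaults follow the usual settings for this workflow: 40 Monte Carlo
#' runs, at most 10 latent variables, 10 CV folds, 80% row subsampling.
#'
#' @param n_mc_runs number of Monte Carlo runs (>= 2).
#' @param max_lv maximum PLSR latent variables.
#' @param n_folds CV folds for RMSECV.
#' @param subsample_fraction fraction of calibration rows drawn each run.
#' @param seed integer seed.
#' @return A `cars_params` list.
#' @export
cars_params <- function(n_mc_runs = 40L, max_lv = 10L, n_folds = 10L,
                        subsample_fraction = 0.8, seed = 1L) {
  if (!is_count(n_mc_runs) || n_mc_runs < 2) stop_nircal("n_mc_runs must be >= 2")
  if (!is_count(n_folds) || n_folds < 2) stop_nircal("n_folds must be >= 2")
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    stop_nircal("subsample_fraction must lie in (0, 1]")
  }
  structure(list(n_mc_runs = as.integer(n_mc_runs),
                 max_lv = as.integer(max_lv),
                 n_folds = as.integer(n_folds),
                 subsample_fraction = subsample_fraction,
                 seed = as.integer(seed)),
            class = "cars_params")
}

#' Parameters for random frog wavelength selection
#'
#' The headline settings are 10000 iterations and the top 40 wavelengths
#' by selection probability; the remaining mechanics (initial subset size,
#' candidate-size spread, worse-candidate acceptance) follow the canonical
#' random frog description and are exposed here.
#'
#' @param n_iterations number of iterations (>= 1).
#' @param n_selected number of wavelengths to return.
#' @param q0 initial subset size.
#' @param theta candidate-size spread: the proposal size is drawn from
#'   `round(Normal(Q, theta * Q))`.
#' @param eta acceptance factor for worse candidates in `[0, 1]`.
#' @param max_lv maximum PLSR latent variables inside the search.
#' @param n_folds CV folds for the per-candidate RMSECV.
#' @param seed integer seed.
#' @param initial_subset optional explicit starting subset (overrides a
#'   random draw of size `q0`); mainly for degenerate-case testing.
#' @return A `frog_params` list.
#' @export
frog_params <- function(n_iterations = 10000L, n_selected = 40L, q0 = 5L,
                        theta = 0.3, eta = 0.1, max_lv = 10L, n_folds = 5L,
                        seed = 1L, initial_subset = NULL) {
  if (!is_count(n_iterations) || n_iterations < 1) {
    stop_nircal("n_iterations must be >= 1")
  }
  if (!is_count(n_selected) || n_selected < 1) {
    stop_nircal("n_selected must be >= 1")
  }
  if (eta < 0 || eta > 1) stop_nircal("eta must lie in [0, 1]")
  structure(list(n_iterations = as.integer(n_iterations),
                 n_selected = as.integer(n_selected), q0 = as.integer(q0),
                 theta = theta, eta = eta, max_lv = as.integer(max_lv),
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 initial_subset = initial_subset),
            class = "frog_params")
}

#' Exponentially decreasing retention ratio (EDF) for CARS
#'
#' `r_i = a * exp(-k * i)` with `a`, `k` fixed by the boundary conditions
#' `r_1 = 1` (all wavelengths retained on the first run) and
#' `r_N = 2 / p` (two retained on the last).
#'
#' @param i run index, `1 <= i <= N`.
#' @param N total number of runs (>= 2).
#' @param p number of wavelengths (>= 3).
#' @return Ratio in (0, 1], strictly decreasing in `i`.
#' @export
#' @examples
#' edf_ratio(1, 40, 1557)   # 1
#' edf_ratio(40, 100, 100)  # 2/p at i = N
edf_ratio <- function(i, N, p) {
  if (p < 3) stop_nircal("EDF schedule undefined for p < 3")
  if (N < 2) stop_nircal("need at least 2 runs")
  if (any(i < 1 | i > N)) stop_nircal("run index out of range")
  k <- log(p / 2) / (N - 1)
  exp(k) * exp(-k * i)
}

#' Adaptive reweighted sampling
#'
#' Draws `n_keep` indices with replacement, with probability proportional
#' to the weights, and returns the distinct indices drawn (sorted). This
#' is the competitive step of CARS: heavily weighted wavelengths survive
#' with near-certainty, lightly weighted ones mostly drop out.
#'
#' @param weights non-negative weights with a positive sum.
#' @param n_keep number of draws (>= 1).
#' @param seed integer seed; `NULL` uses the ambient RNG stream.
#' @return Sorted integer vector of distinct drawn indices.
#' @export
ars_sample <- function(weights, n_keep, seed = NULL) {
  if (any(weights < 0) || any(!is.finite(weights))) {
    stop_nircal("weights must be finite and non-negative")
  }
  if (sum(weights) <= 0) stop_nircal("all weights are zero")
  if (!is_count(n_keep) || n_keep < 1) stop_nircal("n_keep must be >= 1")
  drawn <- with_seed(seed, sample.int(length(weights), n_keep,
                                      replace = TRUE, prob = weights))
  sort(unique(drawn))
}

new_selection_result <- function(selected, method, p, diagnostics) {
  selected <- sort(unique(as.integer(selected)))
  if (length(selected) == 0L) stop_nircal("empty selection")
  if (any(selected < 1L | selected > p)) {
    stop_nircal("selected index outside the wavelength grid")
  }
  structure(list(selected_indices = selected, method = method,
                 n_total = as.integer(p), diagnostics = diagnostics),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(x$method, " selection: ", length(x$selected_indices), " of ",
      x$n_total, " wavelengths (reduction ",
      reduction_percent(length(x$selected_indices), x$n_total), "%)\n",
      sep = "")
  invisible(x)
}

#' CARS wavelength selection
#'
#' Competitive adaptive reweighted sampling: Monte Carlo runs combine an
#' exponentially decreasing enforced-retention schedule with weighted
#' resampling by PLSR coefficient magnitude; the run whose subset attains
#' the lowest 10-fold RMSECV on the calibration block is returned.
#' If competition drives the subset below 2 wavelengths it is frozen at
#' the top 2 by weight for the remaining steps (recorded in the
#' diagnostics, not an error). Deterministic under `params$seed`.
#'
#' @param X calibration predictor matrix (samples x wavelengths, p >= 3).
#' @param y calibration response vector.
#' @param params a [cars_params()].
#' @return A `selection_result`; `diagnostics` holds the per-run retained
#'   counts (`n_retained`), `rmsecv_trace` (length `n_mc_runs`), the
#'   argmin run (`best_run`) and the per-run subsets.
#' @export
cars_select <- function(X, y, params = cars_params()) {
  stopifnot(inherits(params, "cars_params"))
  X <- as_matrix_x(X)
  n <- nrow(X); p <- ncol(X)
  if (p < 3L) stop_nircal("CARS needs at least 3 wavelengths")
  if (n != length(y)) stop_nircal("X rows and y length differ")
  N <- params$n_mc_runs
  n_sub <- max(params$n_folds + 1L,
               as.integer(round(params$subsample_fraction * n)))
  n_sub <- min(n_sub, n)
  retained <- seq_len(p)
  subsets <- vector("list", N)
  trace <- n_retained <- numeric(N)
  frozen <- FALSE
  for (i in seq_len(N)) {
    rs <- derive_seed(params$seed, "cars-run", i)
    sub <- with_seed(rs, sample.int(n, n_sub))
    Xs <- X[sub, retained, drop = FALSE]
    ys <- y[sub]
    lv <- 1L
    if (length(retained) > 1L) {
      cv <- rmsecv(Xs, ys, n_folds = min(params$n_folds, n_sub),
                   max_lv = params$max_lv,
                   seed = derive_seed(rs, "lv"))
      lv <- cv$best_lv
    }
    fit <- pls_core(Xs, ys, lv, scale = TRUE)
    b <- abs(fit$coef[, min(lv, fit$ncomp)])
    w <- if (sum(b) > 0) b / sum(b) else rep(1 / length(b), length(b))
    keep_n <- max(2L, min(as.integer(ceiling(edf_ratio(i, N, p) * p)),
                          length(retained)))
    ord <- order(w, decreasing = TRUE)[seq_len(keep_n)]
    enforced <- retained[ord]
    w_enf <- w[ord]
    if (sum(w_enf) > 0) {
      # canonical ARS: p draws (grid size) from the enforced survivors
      drawn <- ars_sample(w_enf, p, seed = derive_seed(rs, "ars"))
      retained <- sort(enforced[drawn])
    } else {
      retained <- sort(enforced)
    }
    if (length(retained) < 2L) {
      retained <- sort(enforced[seq_len(2L)])
      frozen <- TRUE
    }
    n_retained[i] <- length(retained)
    trace[i] <- rmsecv(X[, retained, drop = FALSE], y,
                       n_folds = min(params$n_folds, n),
                       max_lv = params$max_lv,
                       seed = derive_seed(rs, "score"))$best_rmsecv
    subsets[[i]] <- retained
  }
  best <- which.min(trace)  # earliest run on ties
  new_selection_result(subsets[[best]], "CARS", p,
                       diagnostics = list(n_retained = n_retained,
                                          rmsecv_trace = trace,
                                          best_run = as.integer(best),
                                          subset_frozen = frozen,
                                          subsets = subsets,
                                          params = params))
}

#' Random frog wavelength selection
#'
#' Stochastic subset search: starting from a random subset, each iteration
#' proposes a candidate subset whose size is drawn around the current size
#' (spread `theta`), built by adding random new wavelengths or deleting
#' the least important ones (importance = absolute PLSR coefficient on
#' autoscaled X). The candidate is accepted if its RMSECV does not exceed
#' the current one, otherwise with probability
#' `eta * current_RMSECV / candidate_RMSECV`. Per-wavelength selection
#' frequencies over the iterations rank the wavelengths; the top
#' `n_selected` (ties to the lower index) are returned. Deterministic
#' under `params$seed`.
#'
#' @param X calibration predictor matrix.
#' @param y calibration response vector.
#' @param params a [frog_params()].
#' @return A `selection_result`; `diagnostics$probability` is the
#'   per-wavelength selection probability vector (length `ncol(X)`,
#'   entries in `[0, 1]`).
#' @export
random_frog_select <- function(X, y, params = frog_params()) {
  stopifnot(inherits(params, "frog_params"))
  X <- as_matrix_x(X)
  n <- nrow(X); p <- ncol(X)
  if (n != length(y)) stop_nircal("X rows and y length differ")
  if (params$n_selected > p) {
    stop_nircal("n_selected (", params$n_selected,
                ") exceeds the number of wavelengths (", p, ")")
  }
  nf <- min(params$n_folds, n)
  score <- function(idx) {
    rmsecv(X[, idx, drop = FALSE], y, n_folds = nf,
           max_lv = min(params$max_lv, length(idx)), seed = NULL)$best_rmsecv
  }
  counts <- numeric(p)
  with_seed(params$seed, {
    V <- if (!is.null(params$initial_subset)) {
      sort(unique(as.integer(params$initial_subset)))
    } else {
      sort(sample.int(p, min(params$q0, p)))
    }
    cur <- score(V)
    for (it in seq_len(params$n_iterations)) {
      q <- length(V)
      q_new <- as.integer(round(stats::rnorm(1L, q, params$theta * q)))
      q_new <- max(1L, min(p, q_new))
      if (q_new == q) {
        cand <- V
        cand_cv <- cur
      } else {
        if (q_new < q) {
          fit <- pls_core(X[, V, drop = FALSE], y,
                          min(params$max_lv, q), scale = TRUE)
          imp <- abs(fit$coef[, fit$ncomp])
          cand <- sort(V[order(imp, decreasing = TRUE)[seq_len(q_new)]])
        } else {
          pool <- setdiff(seq_len(p), V)
          add <- pool[sample.int(length(pool), min(q_new - q, length(pool)))]
          cand <- sort(c(V, add))
        }
        cand_cv <- score(cand)
      }
      if (cand_cv <= cur || stats::runif(1L) < params$eta * cur / cand_cv) {
        V <- cand
        cur <- cand_cv
      }
      counts[V] <- counts[V] + 1
    }
  })
  prob <- counts / params$n_iterations
  ord <- order(prob, decreasing = TRUE)  # stable: ties -> lower index
  selected <- sort(ord[seq_len(params$n_selected)])
  new_selection_result(selected, "RandomFrog", p,
                       diagnostics = list(probability = prob,
                                          params = params))
}

#' Wavelength-reduction percentage
#'
#' `100 * (1 - n_selected / n_total)`, rounded to 2 decimals -- the usual
#' way a selector's economy is reported (e.g. 26 of 1557 wavelengths kept
#' is a 98.33% reduction).
#'
#' @param n_selected number of selected wavelengths (> 0).
#' @param n_total grid size (>= n_selected).
#' @return Percentage, rounded to 2 decimals.
#' @export
#' @examples
#' reduction_percent(26, 1557)
reduction_percent <- function(n_selected, n_total) {
  if (!is_count(n_selected) || !is_count(n_total) || n_selected <= 0) {
    stop_nircal("counts must be positive integers")
  }
  if (n_selected > n_total) {
    stop_nircal("n_selected exceeds n_total")
  }
  round(100 * (1 - n_selected / n_total), 2)
}
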