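#' f1 score with the anomaly class positive
#'
#' f1 = tp / (tp + (fp + fn) / 2). When neither the truth nor the
#' predictions contain a positive the score is undefined; it is returned as
#' 0 with a warning rather than NaN so that averaging over resamples stays
#' finite.
#'
#' @param predictions,truths Equal-length binary vectors (1/TRUE =
#'   anomaly).
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' f1_score(c(1, 1, 1, 1, 0), c(1, 1, 1, 0, 1)) # tp 3, fp 1, fn 1 -> 0.75
f1_score <- function(predictions, truths) {
  if (length(predictions) != length(truths)) {
    abort("predictions and truths must have equal length")
  }
  p <- as.logical(predictions)
  t <- as.logical(truths)
  tp <- sum(p & t)
  fp <- sum(p & !t)
  fn <- sum(!p & t)
  if (tp + fp + fn == 0L) {
    warn("no positives in truths or predictions; f1 undefined, returning 0")
    return(0)
  }
  tp / (tp + 0.5 * (fp + fn))
}

#' Evaluate one parameter set on a labelled test set
#'
#' Scores the simulated anomalies (positive class) and the holdout normals
#' (negative class) with [detect_batch()] against the index and returns the
#' f1. The holdout normals must not be part of the index: theta, tau and
#' the neighbour pools are computed from historical records the test set
#' has never seen.
#'
#' @param params An [model_params()].
#' @param index An [build_index()] fitted without the holdout records.
#' @param anomalies Tibble of simulated-anomaly records (nonempty).
#' @param normals Tibble of holdout normal records.
#' @return The f1 score.
#' @export
evaluate_params <- function(params, index, anomalies, normals) {
  if (nrow(anomalies) == 0L) {
    abort("anomaly set is empty; f1 is undefined as an objective")
  }
  test <- dplyr::bind_rows(anomalies, normals)
  det <- detect_batch(test, index, params)
  f1_score(det$verdict == "anomaly",
           c(rep(1L, nrow(anomalies)), rep(0L, nrow(normals))))
}

#' Default search space for the four hyperparameters
#'
#' mu and nu are boxed to (0, 0.1] (at most 10% of the cohort enters a
#' neighbour pool); a and b to (0, 2], wide enough to cover threshold
#' multipliers observed in practice. Lower bounds are strictly positive so
#' every candidate yields usable thresholds.
#'
#' @param mu,nu,a,b Length-2 numeric intervals `c(lo, hi)`.
#' @return Named list of intervals.
#' @export
search_space <- function(mu = c(0.002, 0.1), nu = c(0.002, 0.1),
                         a = c(0.01, 2), b = c(0.01, 2)) {
  space <- list(mu = mu, nu = nu, a = a, b = b)
  for (nm in names(space)) {
    iv <- space[[nm]]
    if (length(iv) != 2L || iv[1] <= 0 || iv[2] <= iv[1]) {
      abort(sprintf("invalid interval for %s", nm))
    }
  }
  if (space$mu[2] > 0.1 || space$nu[2] > 0.1) {
    abort("mu and nu intervals must lie within (0, 0.1]")
  }
  space
}

# --- fast objective ---------------------------------------------------------
# For a fixed index and fixed test records, the distance profiles do not
# depend on (mu, nu, a, b): R(m) and F(n) for every m, n come from the
# cumulative-mean vectors of each record's profile. Candidates are then
# evaluated in O(records), not O(records * S).
profile_matrix <- function(records, index) {
  profs <- lapply(seq_len(nrow(records)), function(k) {
    distance_profile(records[k, , drop = FALSE], index)
  })
  list(
    cum_r = do.call(rbind, lapply(profs, `[[`, "cum_r")),
    cum_f = do.call(rbind, lapply(profs, `[[`, "cum_f")),
    s = profs[[1]]$s
  )
}

flags_for <- function(pm, params, theta, tau) {
  m <- neighbour_size(params$mu, pm$s)
  n <- neighbour_size(params$nu, pm$s)
  r <- pm$cum_r[, m]
  f <- pm$cum_f[, n]
  # type I short-circuits before F, but the flagged set is identical
  r > params$a * theta | f > params$b * tau
}

# --- candidate samplers -----------------------------------------------------
sample_uniform <- function(space, k = 1L) {
  as_tibble(lapply(space, function(iv) runif(k, iv[1], iv[2])))
}

grid_candidates <- function(space, n_evals) {
  per_dim <- max(2L, floor(n_evals^(1 / length(space))))
  axes <- lapply(space, function(iv) seq(iv[1], iv[2], length.out = per_dim))
  grid <- do.call(tidyr::expand_grid, axes)
  head(grid, n_evals)
}

# One TPE-style step: split the observed trials at the gamma quantile of
# the objective, model each dimension of the good and bad sets with a
# Gaussian kernel mixture, and pick — among fresh draws from the good
# mixture — the candidate with the best good/bad density ratio.
tpe_candidate <- function(space, trials, gamma = 0.25, n_draw = 24L) {
  cut <- quantile(trials$f1_mean, probs = 1 - gamma, type = 7)
  good <- trials[trials$f1_mean >= cut, , drop = FALSE]
  bad <- trials[trials$f1_mean < cut, , drop = FALSE]
  if (nrow(good) == 0L || nrow(bad) == 0L) return(sample_uniform(space))

  kde <- function(x, iv) {
    bw <- max(diff(iv) / 20, 1e-9)
    list(
      draw = function(k) {
        centers <- x[sample.int(length(x), k, replace = TRUE)]
        pmin(pmax(rnorm(k, centers, bw), iv[1]), iv[2])
      },
      dens = function(q) {
        vapply(q, function(qi) mean(dnorm(qi, x, bw)) + 1e-12, numeric(1))
      }
    )
  }
  score <- rep(0, n_draw)
  cand <- vector("list", length(space))
  names(cand) <- names(space)
  for (nm in names(space)) {
    g <- kde(good[[nm]], space[[nm]])
    b <- kde(bad[[nm]], space[[nm]])
    draws <- g$draw(n_draw)
    cand[[nm]] <- draws
    score <- score + log(g$dens(draws)) - log(b$dens(draws))
  }
  as_tibble(cand)[which.max(score), , drop = FALSE]
}

#' Tune the distance model's hyperparameters
#'
#' Searches (mu, nu, a, b) for the parameter set maximizing the f1 score on
#' a labelled set of simulated anomalies plus holdout normals. The anomaly
#' set is held fixed; the normal holdout is resampled `n_repeats` times
#' from `normal_pool` and the per-candidate objective is the mean f1 over
#' those resamples, which damps the variance contributed by the small
#' normal class. The same resampled holdouts are reused for every
#' candidate, so candidates are compared on identical data and the whole
#' run is reproducible from `seed`.
#'
#' `normal_pool` (and the anomalies) must be disjoint from the index
#' records: theta, tau and the neighbour pools never see the test data.
#'
#' @param index An [build_index()] fitted on the historical records only.
#' @param anomalies Tibble of labelled simulated anomalies (fixed positive
#'   class).
#' @param normal_pool Tibble of normal records held out from the index,
#'   resampled into holdout sets.
#' @param space A [search_space()].
#' @param n_evals Number of candidate evaluations (default 100).
#' @param n_repeats Number of holdout resamples per candidate (default 50).
#' @param s_n Holdout size per resample; defaults to the anomaly count, so
#'   both classes are similarly sized.
#' @param seed Integer seed controlling the resamples and the search.
#' @param method `"tpe"` (adaptive, default), `"random"` or `"grid"`.
#' @return An object of class `rx_tuning`: `best_params`, `f1_mean`,
#'   `f1_std`, `n_repeats`, `n_evals`, `seed`, `method` and the per-trial
#'   `trace` tibble.
#' @export
tune <- function(index, anomalies, normal_pool, space = search_space(),
                 n_evals = 100L, n_repeats = 50L, s_n = NULL, seed = 1L,
                 method = c("tpe", "random", "grid")) {
  method <- match.arg(method)
  if (n_evals < 1L) abort("n_evals must be at least 1")
  if (nrow(anomalies) == 0L) abort("anomaly set is empty")
  if (nrow(normal_pool) == 0L) abort("normal pool is empty")
  s_n <- s_n %||% min(nrow(anomalies), nrow(normal_pool))
  if (s_n > nrow(normal_pool)) abort("s_n exceeds the normal pool size")

  pm_anom <- profile_matrix(anomalies, index)
  pm_norm <- profile_matrix(normal_pool, index)
  truth <- c(rep(TRUE, nrow(anomalies)), rep(FALSE, s_n))

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  holdouts <- lapply(seq_len(n_repeats), function(r) {
    sample.int(nrow(normal_pool), s_n)
  })

  objective <- function(params) {
    fl_a <- flags_for(pm_anom, params, index$theta, index$tau)
    fl_n <- flags_for(pm_norm, params, index$theta, index$tau)
    f1s <- vapply(holdouts, function(idx) {
      f1_score(c(fl_a, fl_n[idx]), truth)
    }, numeric(1))
    c(mean = mean(f1s), sd = sd(f1s))
  }

  if (method == "grid") {
    cands <- grid_candidates(space, n_evals)
  }
  n_startup <- min(10L, n_evals)
  trace <- tibble(eval = integer(), mu = numeric(), nu = numeric(),
                  a = numeric(), b = numeric(), f1_mean = numeric(),
                  f1_std = numeric())
  for (e in seq_len(n_evals)) {
    cand <- switch(method,
      random = sample_uniform(space),
      grid = cands[e, , drop = FALSE],
      tpe = if (e <= n_startup) sample_uniform(space)
            else tpe_candidate(space, trace)
    )
    if (is.null(cand) || nrow(cand) == 0L) break
    p <- model_params(cand$mu, cand$nu, cand$a, cand$b)
    obj <- objective(p)
    trace <- dplyr::bind_rows(trace, tibble(
      eval = e, mu = p$mu, nu = p$nu, a = p$a, b = p$b,
      f1_mean = obj[["mean"]],
      f1_std = if (is.na(obj[["sd"]])) 0 else obj[["sd"]]
    ))
  }
  best <- trace[which.max(trace$f1_mean), ]
  structure(
    list(
      best_params = model_params(best$mu, best$nu, best$a, best$b),
      f1_mean = best$f1_mean,
      f1_std = best$f1_std,
      n_repeats = n_repeats,
      n_evals = nrow(trace),
      s_n = s_n,
      seed = seed,
      method = method,
      theta = index$theta,
      tau = index$tau,
      s = index$s,
      trace = trace
    ),
    class = "rx_tuning"
  )
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.rx_tuning <- function(x, ...) {
  p <- x$best_params
  cat("<rx_tuning>", x$method, "search,", x$n_evals, "evals x",
      x$n_repeats, "repeats\n")
  cat(sprintf("  best: mu=%.4f nu=%.4f a=%.3f b=%.3f\n", p$mu, p$nu, p$a, p$b))
  cat(sprintf("  f1 = %.3f +/- %.3f\n", x$f1_mean, x$f1_std))
  invisible(x)
}

#' @export
tidy.rx_tuning <- function(x, ...) {
  x$trace
}

#' @export
glance.rx_tuning <- function(x, ...) {
  p <- x$best_params
  tibble(
    mu = p$mu, nu = p$nu, a = p$a, b = p$b,
    f1_mean = x$f1_mean, f1_std = x$f1_std,
    theta = x$theta, tau = x$tau, s = x$s,
    n_evals = x$n_evals, n_repeats = x$n_repeats,
    method = x$method, seed = x$seed
  )
}

#' Save tuned parameters as JSON
#'
#' @param tuning An `rx_tuning` result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(tuning, path) {
  jsonlite::write_json(as.list(glance(tuning)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load tuned parameters saved by [write_params()]
#'
#' @param path Path to the JSON file.
#' @param validate Enforce the training-time mu/nu box.
#' @return An [model_params()] object with theta/tau attributes.
#' @export
read_params <- function(path, validate = TRUE) {
  p <- jsonlite::fromJSON(path)
  out <- model_params(p$mu, p$nu, p$a, p$b, validate = validate)
  attr(out, "theta") <- p$theta
  attr(out, "tau") <- p$tau
  out
}
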