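#' Specify a hidden Markov model with mixed emission streams
#'
#' States emit independent observations on one or more named data streams.
#' Supported families: `"gamma"` (parametrized by mean and sd, optionally
#' zero-inflated with a per-state point mass at zero) and `"bernoulli"`.
#' Transition probabilities follow a multinomial-logit parametrization with
#' the diagonal (staying) as reference; logits are linear in the covariates
#' of `transition` (a one-sided formula evaluated on the data, e.g.
#' `~ current + id`). Missing stream values are allowed and marginalized by
#' the forward algorithm.
#'
#' @param n_states number of hidden states K (>= 1).
#' @param streams named list; each element is
#'   `list(family = "gamma", zero_inflated = FALSE)` or
#'   `list(family = "bernoulli")`.
#' @param transition one-sided formula for the transition-logit design
#'   (default `~ 1`, homogeneous chain).
#' @return object of class `hmm_spec`.
#' @export
hmm_spec <- function(n_states, streams, transition = ~1) {
  stopifnot(n_states >= 1, length(streams) >= 1, !is.null(names(streams)))
  for (s in streams) {
    if (!s$family %in% c("gamma", "bernoulli")) {
      stop("unsupported emission family: ", s$family)
    }
  }
  structure(list(n_states = as.integer(n_states), streams = streams,
                 transition = transition),
            class = "hmm_spec")
}

#' Gamma mean/sd to shape/scale conversion (and back)
#'
#' `shape = mean^2 / sd^2`, `scale = sd^2 / mean`; both must be finite and
#' positive.
#'
#' @param mean,sd Gamma mean and standard deviation (> 0).
#' @param shape,scale Gamma shape and scale (> 0).
#' @return list with `shape` and `scale` (or `mean` and `sd`).
#' @export
gamma_shape_scale <- function(mean, sd) {
  stopifnot(all(mean > 0), all(sd > 0))
  list(shape = mean^2 / sd^2, scale = sd^2 / mean)
}

#' @rdname gamma_shape_scale
#' @export
gamma_mean_sd <- function(shape, scale) {
  stopifnot(all(shape > 0), all(scale > 0))
  list(mean = shape * scale, sd = sqrt(shape) * scale)
}

# ---- parameter packing -------------------------------------------------

n_beta_cols <- function(K) K * (K - 1L)

# enumeration of off-diagonal transitions: (i -> j) for i in 1..K, j != i
.offdiag_cache <- new.env(parent = emptyenv())
offdiag_index <- function(K) {
  key <- as.character(K)
  cached <- get0(key, envir = .offdiag_cache)
  if (!is.null(cached)) return(cached)
  idx <- expand.grid(j = seq_len(K), i = seq_len(K))[, c("i", "j")]
  idx <- idx[idx$i != idx$j, ]
  assign(key, idx, envir = .offdiag_cache)
  idx
}

pack_params <- function(spec, par) {
  w <- c()
  for (nm in names(spec$streams)) {
    st <- spec$streams[[nm]]
    pe <- par$emission[[nm]]
    if (st$family == "gamma") {
      w <- c(w, log(pe$mean), log(pe$sd))
      if (isTRUE(st$zero_inflated)) w <- c(w, stats::qlogis(pe$zero))
    } else {
      w <- c(w, stats::qlogis(pe$prob))
    }
  }
  c(w, as.numeric(par$beta))
}

unpack_params <- function(spec, w, n_cov) {
  K <- spec$n_states
  pos <- 1L
  take <- function(n) {
    out <- w[pos:(pos + n - 1L)]
    pos <<- pos + n
    out
  }
  emission <- list()
  for (nm in names(spec$streams)) {
    st <- spec$streams[[nm]]
    if (st$family == "gamma") {
      e <- list(mean = exp(take(K)), sd = exp(take(K)))
      if (isTRUE(st$zero_inflated)) e$zero <- stats::plogis(take(K))
      emission[[nm]] <- e
    } else {
      emission[[nm]] <- list(prob = stats::plogis(take(K)))
    }
  }
  beta <- matrix(take(n_cov * n_beta_cols(K)), nrow = n_cov)
  list(emission = emission, beta = beta)
}

# ---- model pieces ------------------------------------------------------

# T x K matrix of per-bin emission densities (product over streams,
# NA contributes 1), floored to keep the forward recursion finite.
emission_density <- function(spec, par, data) {
  K <- spec$n_states
  n <- nrow(data)
  dens <- matrix(1, n, K)
  for (nm in names(spec$streams)) {
    st <- spec$streams[[nm]]
    x <- data[[nm]]
    if (is.null(x)) stop("data lacks stream column '", nm, "'")
    obs <- !is.na(x)
    pe <- par$emission[[nm]]
    for (k in seq_len(K)) {
      if (st$family == "gamma") {
        if (any(pe$mean[k] <= 0) || any(pe$sd[k] <= 0)) {
          stop("gamma parameters must be positive")
        }
        gs <- gamma_shape_scale(pe$mean[k], pe$sd[k])
        dk <- stats::dgamma(x[obs], shape = gs$shape, scale = gs$scale)
        if (isTRUE(st$zero_inflated)) {
          z <- x[obs] == 0
          dk[z] <- pe$zero[k]
          dk[!z] <- (1 - pe$zero[k]) * dk[!z]
        }
      } else {
        dk <- numeric(sum(obs))
        one <- x[obs] == 1
        dk[one] <- pe$prob[k]
        dk[!one] <- 1 - pe$prob[k]
      }
      dens[obs, k] <- dens[obs, k] * pmax(dk, 1e-300)
    }
  }
  dens
}

# K x K x T transition array from the multinomial-logit design.
# Row t is the matrix used to transition INTO bin t.
transition_array <- function(spec, par, X) {
  K <- spec$n_states
  n <- nrow(X)
  if (K == 1L) return(array(1, c(1, 1, n)))
  eta <- X %*% par$beta                 # n x K(K-1)
  w <- exp(pmin(eta, 500))
  idx <- offdiag_index(K)
  A <- array(0, c(K, K, n))
  for (i in seq_len(K)) A[i, i, ] <- 1  # diagonal reference weight 1
  for (c_ in seq_len(nrow(idx))) {
    A[idx$i[c_], idx$j[c_], ] <- w[, c_]
  }
  for (i in seq_len(K)) {
    rs <- colSums(matrix(A[i, , ], nrow = K))   # per-bin row sums
    for (j in seq_len(K)) A[i, j, ] <- A[i, j, ] / rs
  }
  A
}

# single K x K transition matrix at one covariate row
transition_matrix_at <- function(spec, par, xrow) {
  A <- transition_array(spec, par, matrix(xrow, nrow = 1))
  matrix(A[, , 1], spec$n_states, spec$n_states)
}

# initial distribution: stationary distribution of the transition matrix at
# the covariate design means (or as overridden in par$delta)
initial_distribution <- function(spec, par, X) {
  if (!is.null(par$delta)) return(par$delta)
  if (spec$n_states == 1L) return(1)
  G <- transition_matrix_at(spec, par, colMeans(X))
  d <- markov_stationary(G)
  pmax(d, 1e-12) / sum(pmax(d, 1e-12))
}

build_design <- function(spec, data) {
  mf <- stats::model.frame(spec$transition, data, na.action = stats::na.fail)
  stats::model.matrix(spec$transition, mf)
}

# Precompute the pieces of the likelihood that do not depend on parameters:
# design matrix, per-sequence row blocks, and whether the design is constant
# within each sequence (then one transition matrix serves the whole block).
hmm_prepare <- function(spec, data, sequence = NULL) {
  X <- build_design(spec, data)
  seq_f <- if (is.null(sequence)) rep(1L, nrow(data)) else
    as.integer(factor(data[[sequence]], levels = unique(data[[sequence]])))
  rows <- split(seq_len(nrow(data)), seq_f)
  const <- vapply(rows, function(r) {
    Xs <- X[r, , drop = FALSE]
    nrow(Xs) == 1L ||
      all(abs(sweep(Xs[-1, , drop = FALSE], 2, Xs[1, ])) < 1e-12)
  }, logical(1))
  list(X = X, rows = rows, const = const, xbar = colMeans(X))
}

hmm_delta <- function(spec, par, xbar) {
  if (!is.null(par$delta)) return(par$delta)
  if (spec$n_states == 1L) return(1)
  G <- transition_matrix_at(spec, par, xbar)
  d <- markov_stationary(G)
  pmax(d, 1e-12) / sum(pmax(d, 1e-12))
}

hmm_loglik_prepared <- function(spec, par, data, prep) {
  dens <- emission_density(spec, par, data)
  delta <- hmm_delta(spec, par, prep$xbar)
  ll <- 0
  for (si in seq_along(prep$rows)) {
    r <- prep$rows[[si]]
    Xs <- if (prep$const[si]) prep$X[r[1], , drop = FALSE] else
      prep$X[r, , drop = FALSE]
    A <- transition_array(spec, par, Xs)
    ll <- ll + forward_loglik_cpp(dens[r, , drop = FALSE], A, delta)
  }
  ll
}

#' Forward log-likelihood of an HMM
#'
#' Scaled forward recursion; independent sequences (animals) contribute the
#' sum of their log-likelihoods. Missing stream values contribute likelihood
#' one in their bin, so a bin with all streams missing is uninformative.
#'
#' @param spec an [hmm_spec()].
#' @param par parameter list: `emission` (per-stream per-state natural-scale
#'   parameters), `beta` (transition-logit coefficient matrix, rows =
#'   design columns, columns = off-diagonal transitions), optional `delta`.
#' @param data data.frame containing the stream columns, transition
#'   covariates, and the sequence id column.
#' @param sequence name of the sequence id column (`NULL` = one sequence).
#' @return total log-likelihood (scalar).
#' @export
forward_loglik <- function(spec, par, data, sequence = NULL) {
  prep <- hmm_prepare(spec, data, sequence)
  hmm_loglik_prepared(spec, par, data, prep)
}

#' Viterbi decoding of the most probable state sequence
#'
#' Jointly most probable path per sequence, in log space; ties are broken
#' toward the lower state index. Missing values are handled as in
#' [forward_loglik()].
#'
#' @param fit a `fitted_hmm` (or a list with `spec` and `par`).
#' @param data data.frame aligned with the fit's streams and covariates.
#' @param sequence sequence id column name (`NULL` = one sequence).
#' @return integer state vector (1..K), one entry per data row.
#' @export
viterbi_decode <- function(fit, data, sequence = NULL) {
  spec <- fit$spec; par <- fit$par
  prep <- hmm_prepare(spec, data, sequence)
  dens <- emission_density(spec, par, data)
  delta <- hmm_delta(spec, par, prep$xbar)
  out <- integer(nrow(data))
  for (si in seq_along(prep$rows)) {
    r <- prep$rows[[si]]
    Xs <- if (prep$const[si]) prep$X[r[1], , drop = FALSE] else
      prep$X[r, , drop = FALSE]
    A <- transition_array(spec, par, Xs)
    out[r] <- viterbi_cpp(log(dens[r, , drop = FALSE]), log(A), log(delta))
  }
  out
}

# moment-based initial emission parameters: quantile-split per stream
init_emission <- function(spec, data) {
  K <- spec$n_states
  emission <- list()
  for (nm in names(spec$streams)) {
    st <- spec$streams[[nm]]
    x <- data[[nm]]
    x <- x[!is.na(x)]
    if (st$family == "gamma") {
      pos <- x[x > 0]
      if (length(pos) < K) pos <- pmax(x, 1e-3)
      qs <- stats::quantile(pos, probs = seq(0, 1, length.out = K + 1))
      grp <- cut(pos, breaks = unique(c(-Inf, qs[-c(1, K + 1)], Inf)),
                 labels = FALSE)
      mu <- tapply(pos, grp, mean)
      sg <- tapply(pos, grp, stats::sd)
      mu <- as.numeric(mu); sg <- as.numeric(sg)
      if (length(mu) < K) { mu <- rep_len(mu, K); sg <- rep_len(sg, K) }
      sg[!is.finite(sg) | sg <= 0] <- mu[!is.finite(sg) | sg <= 0] / 2
      e <- list(mean = pmax(mu, 1e-6), sd = pmax(sg, 1e-6))
      if (isTRUE(st$zero_inflated)) {
        e$zero <- rep(min(max(mean(x == 0), 0.01), 0.95), K)
      }
      emission[[nm]] <- e
    } else {
      emission[[nm]] <- list(prob = seq(0.2, 0.8, length.out = max(K, 2))[
        seq_len(K)])
    }
  }
  emission
}

#' Fit an HMM by direct numerical maximum likelihood
#'
#' Maximizes the forward log-likelihood over unconstrained working
#' parameters (log means and sds, logit probabilities and zero-mass weights,
#' free transition-logit coefficients) with BFGS and numerical gradients.
#' Multiple jittered restarts guard against local optima; the best
#' log-likelihood wins. Initial emission parameters default to
#' quantile-split moment estimates.
#'
#' @param spec an [hmm_spec()].
#' @param data data.frame with stream and covariate columns.
#' @param sequence sequence id column name (`NULL` = one sequence).
#' @param par0 optional initial parameter list (as in [forward_loglik()]).
#' @param nstarts number of starts (first unjittered; default 5).
#' @param seed seed for the jitter.
#' @param jitter_sd working-scale jitter sd for restarts.
#' @param control passed to [stats::optim()] (`maxit`, `reltol`).
#' @return object of class `fitted_hmm`: `spec`, `par`, `logL`, `npar`,
#'   `AIC`, `convergence`, `n_obs`, `start_logL`, `design` (column names).
#' @export
fit_hmm <- function(spec, data, sequence = NULL, par0 = NULL, nstarts = 5,
                    seed = 1, jitter_sd = 0.2,
                    control = list(maxit = 2000, reltol = 1e-8)) {
  X <- build_design(spec, data)
  n_cov <- ncol(X)
  K <- spec$n_states
  if (is.null(par0)) {
    beta0 <- matrix(0, n_cov, n_beta_cols(K))
    if (K > 1) beta0[1, ] <- log(0.05)   # sticky chain to start
    par0 <- list(emission = init_emission(spec, data), beta = beta0)
  }
  w0 <- pack_params(spec, par0)

  prep <- hmm_prepare(spec, data, sequence)
  negll <- function(w) {
    par <- unpack_params(spec, w, n_cov)
    # extreme line-search excursions produce NaN densities; they are
    # rejected via the penalty value, so their warnings are noise
    ll <- tryCatch(suppressWarnings(
      hmm_loglik_prepared(spec, par, data, prep)),
      error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  set.seed(seed)
  best <- NULL
  start_ll <- -negll(w0)
  for (s in seq_len(nstarts)) {
    ws <- if (s == 1) w0 else w0 + stats::rnorm(length(w0), 0, jitter_sd)
    opt <- tryCatch(
      stats::optim(ws, negll, method = "BFGS", control = control),
      error = function(e) NULL
    )
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("HMM fitting failed on all starts")
  par <- unpack_params(spec, best$par, n_cov)
  logL <- -best$value
  npar <- length(best$par)
  structure(list(spec = spec, par = par, logL = logL, npar = npar,
                 AIC = 2 * npar - 2 * logL, convergence = best$convergence,
                 n_obs = nrow(data), start_logL = start_ll,
                 design = colnames(X), sequence = sequence),
            class = "fitted_hmm")
}

#' @export
print.fitted_hmm <- function(x, ...) {
  cat(sprintf("Fitted HMM: %d states, %d parameters\n", x$spec$n_states,
              x$npar))
  cat(sprintf("  logL = %.3f  AIC = %.3f  (n = %d bins)\n", x$logL, x$AIC,
              x$n_obs))
  for (nm in names(x$par$emission)) {
    e <- x$par$emission[[nm]]
    if (!is.null(e$mean)) {
      cat(sprintf("  %s: mean %s | sd %s\n", nm,
                  paste(signif(e$mean, 3), collapse = " "),
                  paste(signif(e$sd, 3), collapse = " ")))
    } else {
      cat(sprintf("  %s: p %s\n", nm,
                  paste(signif(e$prob, 3), collapse = " ")))
    }
  }
  invisible(x)
}

#' Rank fitted HMMs by AIC
#'
#' @param fits named list of `fitted_hmm` objects fitted to the same data.
#' @return data.frame ordered by ascending AIC with `dAIC`; ties keep entry
#'   order.
#' @export
rank_models <- function(fits) {
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  nobs <- vapply(fits, function(f) f$n_obs, numeric(1))
  if (length(unique(nobs)) > 1) {
    stop("models were fitted on different observation sets")
  }
  tab <- data.frame(model = names(fits),
                    npar = vapply(fits, function(f) f$npar, numeric(1)),
                    logL = vapply(fits, function(f) f$logL, numeric(1)),
                    AIC = vapply(fits, function(f) f$AIC, numeric(1)),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$AIC, seq_len(nrow(tab))), ]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  tab
}

#' Simulate observations from an HMM
#'
#' States follow the (possibly covariate-dependent) chain; the initial state
#' is drawn from the stationary distribution at the covariate means.
#'
#' @param spec an [hmm_spec()].
#' @param par parameter list.
#' @param n_seq number of independent sequences.
#' @param len bins per sequence.
#' @param covariates optional data.frame of `n_seq * len` covariate rows
#'   (ordered by sequence); default intercept-only.
#' @param seed integer seed.
#' @return data.frame with `id`, stream columns, `state`, plus covariates.
#' @export
simulate_hmm <- function(spec, par, n_seq, len, covariates = NULL, seed = 1) {
  set.seed(seed)
  K <- spec$n_states
  total <- n_seq * len
  if (is.null(covariates)) {
    covariates <- data.frame(row.names = seq_len(total))
  }
  covariates$id <- rep(sprintf("A%02d", seq_len(n_seq)), each = len)
  X <- build_design(spec, covariates)
  A <- transition_array(spec, par, X)
  delta <- initial_distribution(spec, par, X)
  out <- covariates
  out$state <- NA_integer_
  for (nm in names(spec$streams)) out[[nm]] <- NA_real_
  for (s in seq_len(n_seq)) {
    rows <- ((s - 1) * len + 1):(s * len)
    st <- integer(len)
    st[1] <- sample.int(K, 1, prob = delta)
    for (t in 2:len) {
      st[t] <- sample.int(K, 1, prob = A[st[t - 1], , rows[t]])
    }
    out$state[rows] <- st
  }
  for (nm in names(spec$streams)) {
    stp <- spec$streams[[nm]]
    pe <- par$emission[[nm]]
    k <- out$state
    if (stp$family == "gamma") {
      gs <- gamma_shape_scale(pe$mean[k], pe$sd[k])
      x <- stats::rgamma(total, shape = gs$shape, scale = gs$scale)
      if (isTRUE(stp$zero_inflated)) {
        x[stats::runif(total) < pe$zero[k]] <- 0
      }
      out[[nm]] <- x
    } else {
      out[[nm]] <- as.numeric(stats::runif(total) < pe$prob[k])
    }
  }
  out
}

#' Permute the state labels of a parameter set or fitted model
#'
#' `perm[k]` gives the old state index that becomes new state `k`. Emission
#' parameters are reordered and transition-logit columns remapped
#' accordingly (the diagonal-reference parametrization is closed under
#' permutation). Useful for post-fit relabelling to a semantic state order.
#'
#' @param fit a `fitted_hmm`.
#' @param perm integer permutation of `1:K`.
#' @return the fit with permuted parameters.
#' @export
permute_states <- function(fit, perm) {
  spec <- fit$spec; K <- spec$n_states
  stopifnot(length(perm) == K, setequal(perm, seq_len(K)))
  par <- fit$par
  for (nm in names(par$emission)) {
    par$emission[[nm]] <- lapply(par$emission[[nm]], function(v) v[perm])
  }
  idx <- offdiag_index(K)
  key <- paste(idx$i, idx$j)
  new_key <- paste(perm[idx$i], perm[idx$j])
  par$beta <- par$beta[, match(new_key, key), drop = FALSE]
  fit$par <- par
  fit$relabelled <- perm
  fit
}
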