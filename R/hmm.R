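#' Expected log2 ratio of a copy number state
#'
#' Under the cfDNA mixture model, a bin with tumour copy number `c` in a
#' sample with tumour fraction `f` and tumour ploidy `phi` has expected
#' depth proportional to `f*c + (1-f)*2`; relative to the sample-average
#' depth `f*phi + (1-f)*2` the expected log2 ratio is
#' `log2((f*c + (1-f)*2) / (f*phi + (1-f)*2))`.
#'
#' @param c Integer copy number state(s).
#' @param f Tumour fraction in \[0, 1\].
#' @param phi Tumour ploidy (> 0).
#' @param floor Value returned where the mixture numerator is zero
#'   (homozygous deletion at f = 1).
#' @return Expected log2 ratio, vectorised over `c`.
#' @export
emission_mean <- function(c, f, phi, floor = -8) {
  if (f < 0 || f > 1) stop("f must be in [0, 1]", call. = FALSE)
  if (phi <= 0) stop("phi must be positive", call. = FALSE)
  num <- f * c + (1 - f) * 2
  denom <- f * phi + (1 - f) * 2
  if (denom <= 0) stop("degenerate mixture: average depth is zero", call. = FALSE)
  out <- ifelse(num <= 0, floor, log2(pmax(num, 2^floor * denom) / denom))
  unname(out)
}

#' Continuous absolute tumour copy number from a log2 ratio
#'
#' Inverse of [emission_mean()]:
#' `((f*phi + (1-f)*2) * 2^r - (1-f)*2) / f`.
#'
#' @param log2_ratio Observed log2 ratio(s).
#' @param f Tumour fraction (must be > 0; at f = 0 the tumour copy number
#'   is undefined).
#' @param phi Tumour ploidy.
#' @return Continuous tumour copy number, vectorised.
#' @export
absolute_copy_number <- function(log2_ratio, f, phi) {
  if (f <= 0) stop("undefined operation: absolute copy number requires f > 0",
                   call. = FALSE)
  ((f * phi + (1 - f) * 2) * 2^log2_ratio - (1 - f) * 2) / f
}

#' HMM parameter bundle
#'
#' @param f Tumour fraction.
#' @param phi Tumour ploidy.
#' @param sd Emission standard deviation (shared Gaussian sd of log2
#'   ratios around their state means).
#' @param states Ordered integer CN states (default 0..5; higher-level
#'   amplifications are handled at 50 kb by the focal caller).
#' @param self_transition Per-bin probability of staying in the same state
#'   (default 0.9999: expected segment length ~5 Mb at 500 kb bins).
#' @return An `hmm_params` list.
#' @export
hmm_params <- function(f, phi, sd, states = 0:5, self_transition = 0.9999) {
  stopifnot(sd > 0, self_transition > 0, self_transition < 1)
  structure(list(f = f, phi = phi, sd = sd, states = states,
                 self_transition = self_transition),
            class = "hmm_params")
}

transition_matrix <- function(K, self) {
  m <- matrix((1 - self) / (K - 1), K, K)
  diag(m) <- self
  m
}

# Split the valid bins of a ratio object into per-chromosome index chains.
chain_indices <- function(ratios, grid) {
  valid <- which(ratios$valid)
  if (length(valid) < 1) stop("insufficient data: no valid bins", call. = FALSE)
  if (any(!is.finite(ratios$log2_ratio[valid])))
    stop("invalid input: non-finite log2 ratio in a valid bin", call. = FALSE)
  split(valid, factor(grid$chrom[valid], levels = unique(grid$chrom)))
}

#' Viterbi copy number state path
#'
#' Maximum a-posteriori CN path under Gaussian emissions with means
#' [emission_mean()] and a shared sd. Chromosomes are independent chains
#' (no transition across chromosome boundaries); ties break toward the
#' state closest to neutral CN 2.
#'
#' @param ratios A `normalized_ratios` object.
#' @param params An `hmm_params` bundle.
#' @param grid The `bin_grid`.
#' @return Integer per-bin copy number (NA in masked bins).
#' @export
viterbi_states <- function(ratios, params, grid) {
  chains <- chain_indices(ratios, grid)
  K <- length(params$states)
  mu <- emission_mean(params$states, params$f, params$phi)
  logtrans <- log(transition_matrix(K, params$self_transition))
  loginit <- rep(-log(K), K)
  ndist <- abs(params$states - 2)
  cn <- rep(NA_integer_, length(ratios$log2_ratio))
  for (idx in chains) {
    r <- ratios$log2_ratio[idx]
    logemis <- vapply(mu, function(m) stats::dnorm(r, m, params$sd, log = TRUE),
                      numeric(length(r)))
    if (is.null(dim(logemis))) logemis <- matrix(logemis, nrow = length(r))
    path <- .viterbi_chain(logemis, logtrans, loginit, ndist)
    cn[idx] <- params$states[path]
  }
  cn
}

# Forward-backward over all chromosome chains.
# Returns per-bin posteriors over states (rows = all bins; NA rows for
# masked bins) and the total log-likelihood.
forward_backward <- function(ratios, params, grid) {
  chains <- chain_indices(ratios, grid)
  K <- length(params$states)
  mu <- emission_mean(params$states, params$f, params$phi)
  trans <- transition_matrix(K, params$self_transition)
  init <- rep(1 / K, K)
  gamma <- matrix(NA_real_, length(ratios$log2_ratio), K)
  ll <- 0
  for (idx in chains) {
    r <- ratios$log2_ratio[idx]
    emis <- vapply(mu, function(m) stats::dnorm(r, m, params$sd),
                   numeric(length(r)))
    if (is.null(dim(emis))) emis <- matrix(emis, nrow = length(r))
    emis <- pmax(emis, 1e-300)
    res <- .fb_chain(emis, trans, init)
    gamma[idx, ] <- res$gamma
    ll <- ll + res$loglik
  }
  list(gamma = gamma, loglik = ll)
}

#' Fit tumour fraction, ploidy and emission sd by EM
#'
#' Alternates an E-step (forward-backward responsibilities over CN states)
#' with an M-step in which the emission sd has a closed form given (f, phi)
#' and (f, phi) are updated by bounded 2-D numerical maximisation of the
#' expected complete-data log-likelihood. The observed-data log-likelihood
#' is checked to be non-decreasing.
#'
#' @param ratios A `normalized_ratios` object.
#' @param grid The `bin_grid`.
#' @param init_f Initial tumour fraction in (0, 1\].
#' @param init_phi Initial ploidy (grid default uses 2 and 3).
#' @param hyper `list(self_transition=, max_iter=, tol=)`.
#' @param states Integer CN states.
#' @return A `fit_solution`: hmm_params fields plus `loglik`,
#'   `nonneutral_fraction` (fraction of valid genome length with Viterbi
#'   CN != 2) and `n_iter`.
#' @export
em_fit <- function(ratios, grid, init_f, init_phi,
                   hyper = list(self_transition = 0.9999, max_iter = 30,
                                tol = 1e-3),
                   states = 0:5) {
  stopifnot(init_f > 0, init_f <= 1)
  valid <- ratios$valid
  r_all <- ratios$log2_ratio[valid]
  n <- length(r_all)
  f <- init_f; phi <- init_phi
  sigma <- max(stats::sd(r_all) / 2, 0.02)

  q_objective <- function(par, gamma_v) {
    mu <- emission_mean(states, par[1], par[2])
    resid2 <- 0
    for (k in seq_along(states))
      resid2 <- resid2 + sum(gamma_v[, k] * (r_all - mu[k])^2)
    # sigma profiled out: maximised Q is -n/2 * log(resid2/n) + const
    n * log(resid2 / n)
  }

  ll_old <- -Inf
  iters <- 0
  for (it in seq_len(hyper$max_iter)) {
    params <- hmm_params(f, phi, sigma, states, hyper$self_transition)
    e <- forward_backward(ratios, params, grid)
    ll <- e$loglik
    if (ll < ll_old - 1e-3 * (1 + abs(ll_old)))
      stop("internal error: EM log-likelihood decreased (", ll_old, " -> ",
           ll, ")", call. = FALSE)
    iters <- it
    converged <- is.finite(ll_old) && (ll - ll_old) < hyper$tol
    ll_old <- ll
    if (converged) break

    gamma_v <- e$gamma[valid, , drop = FALSE]
    # box around the initialisation keeps each restart in its own basin,
    # so the restart grid explores genuinely distinct solutions
    opt <- stats::optim(c(f, phi), q_objective, gamma_v = gamma_v,
                        method = "L-BFGS-B",
                        lower = c(max(1e-3, init_f / 2), init_phi - 0.6),
                        upper = c(min(1, init_f * 2), init_phi + 0.6))
    f <- opt$par[1]; phi <- opt$par[2]
    mu <- emission_mean(states, f, phi)
    resid2 <- 0
    for (k in seq_along(states))
      resid2 <- resid2 + sum(gamma_v[, k] * (r_all - mu[k])^2)
    sigma <- max(sqrt(resid2 / n), 1e-4)
  }

  params <- hmm_params(f, phi, sigma, states, hyper$self_transition)
  cn <- viterbi_states(ratios, params, grid)
  len <- bin_lengths(grid)
  lv <- len[valid]; cnv <- cn[!is.na(cn)]
  nonneutral <- sum(lv[cnv != 2]) / sum(lv)
  # aberration load: length-weighted mean |CN - 2|; a graded version of the
  # non-neutral fraction that also separates mirror solutions relabelling
  # single-copy events as two-copy events at half the tumour fraction
  load <- sum(lv * abs(cnv - 2)) / sum(lv)
  structure(list(f = f, phi = phi, sd = sigma, states = states,
                 self_transition = hyper$self_transition,
                 loglik = ll_old, nonneutral_fraction = nonneutral,
                 aberration_load = load, n_iter = iters, bin_cn = cn,
                 init_f = init_f, init_phi = init_phi),
            class = "fit_solution")
}

#' Profile estimation configuration
#'
#' @param f_grid Tumour-fraction initialisations for the EM restarts.
#' @param phi_grid Ploidy initialisations.
#' @param f_min Below this best-fit fraction the sample is called
#'   zero-ctDNA.
#' @param min_nonneutral Minimum fraction of the genome in non-neutral
#'   states for a detectable profile.
#' @param lambda Model-selection penalty: the selected solution maximises
#'   `loglik - lambda * aberration_load` where the load is the
#'   length-weighted mean |CN - 2| of the Viterbi path. Among solutions of
#'   near-equal likelihood (whole-genome relabellings, half-fraction
#'   double-copy mirrors) this prefers the most parsimonious aberration
#'   pattern; kept small so genuine likelihood differences dominate.
#' @param spacing_min_sd Resolution floor: solutions whose per-copy level
#'   spacing is below this multiple of the fitted emission sd are rejected
#'   (states closer than this are statistically unresolvable and such fits
#'   merely absorb noise). Sets an effective tumour-fraction detection
#'   floor of roughly `spacing_min_sd * sd * 2 * ln(2)`.
#' @param self_transition,max_iter,tol EM hyperparameters.
#' @param states Integer CN states.
#' @return Config list for [estimate_profile()].
#' @export
profile_config <- function(f_grid = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
                           phi_grid = c(2, 3), f_min = 0.03,
                           min_nonneutral = 0.01, lambda = 4,
                           spacing_min_sd = 0.35,
                           self_transition = 0.9999, max_iter = 30,
                           tol = 1e-3, states = 0:5) {
  list(f_grid = f_grid, phi_grid = phi_grid, f_min = f_min,
       min_nonneutral = min_nonneutral, lambda = lambda,
       spacing_min_sd = spacing_min_sd,
       self_transition = self_transition, max_iter = max_iter, tol = tol,
       states = states)
}

# Refine a fitted solution's (f, phi) by maximising the count-level
# negative binomial likelihood of its state path, alternating with path
# refreshes. The Gaussian EM estimate is slightly biased by the asymmetry
# the log2 transform leaves in count noise; the count-level polish removes
# it. The alternation is run from both the EM estimate and the original
# grid initialisation (coordinate ascent can self-confirm a shrunken f)
# and the better count-likelihood result is kept.
# Winsorized negative-binomial log-likelihood: each bin's deviance from
# its saturated fit is capped, so a handful of extreme bins (and the
# incentive to spread boundary-state misfit into a whole-genome parameter
# compromise) cannot dominate candidate comparisons.
nb_loglik_capped <- function(x, mu, size, cap = 8) {
  ll <- stats::dnbinom(x, mu = mu, size = size, log = TRUE)
  sat <- stats::dnbinom(x, mu = pmax(x, 1e-8), size = size, log = TRUE)
  sum(sat - pmin(sat - ll, cap))
}

nb_polish <- function(s, ratios, grid, counts, iters = 2) {
  e0_all <- counts$counts / 2^ratios$log2_ratio

  run_from <- function(f0, phi0) {
    f <- f0; phi <- phi0; sd_ <- s$sd
    params <- hmm_params(f, phi, sd_, s$states, s$self_transition)
    cn <- viterbi_states(ratios, params, grid)
    nb_final <- -Inf
    for (it in seq_len(iters)) {
      idx <- which(!is.na(cn))
      e0 <- e0_all[idx]
      path_states <- cn[idx]
      nb_ll <- function(f, phi, size) {
        mu_st <- emission_mean(s$states, f, phi)
        mu_i <- e0 * 2^mu_st[match(path_states, s$states)]
        nb_loglik_capped(counts$counts[idx], mu_i, size)
      }
      size_hat <- exp(stats::optimize(function(ls) nb_ll(f, phi, exp(ls)),
                                      c(log(5), log(1e7)),
                                      maximum = TRUE)$maximum)
      opt <- stats::optim(c(f, phi), function(p) -nb_ll(p[1], p[2], size_hat),
                          method = "L-BFGS-B",
                          lower = c(max(1e-3, f / 1.5), phi - 0.3),
                          upper = c(min(1, f * 1.5), phi + 0.3))
      f <- opt$par[1]; phi <- opt$par[2]
      nb_final <- -opt$value
      mu_st <- emission_mean(s$states, f, phi)
      resid <- ratios$log2_ratio[idx] - mu_st[match(path_states, s$states)]
      sd_ <- max(stats::sd(resid), 1e-4)
      params <- hmm_params(f, phi, sd_, s$states, s$self_transition)
      cn <- viterbi_states(ratios, params, grid)
    }
    list(f = f, phi = phi, sd = sd_, cn = cn, nb = nb_final)
  }

  a <- run_from(s$f, s$phi)
  b <- run_from(s$init_f, s$init_phi)
  r_best <- if (a$nb >= b$nb) a else b
  s$f <- r_best$f; s$phi <- r_best$phi; s$sd <- r_best$sd
  s$bin_cn <- r_best$cn
  len <- bin_lengths(grid)
  valid <- !is.na(s$bin_cn)
  lv <- len[valid]; cnv <- s$bin_cn[valid]
  s$nonneutral_fraction <- sum(lv[cnv != 2]) / sum(lv)
  s$aberration_load <- sum(lv * abs(cnv - 2)) / sum(lv)
  s
}

segments_from_path <- function(cn, ratios, grid) {
  valid <- which(!is.na(cn))
  if (length(valid) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      cn = integer(), mean_log2 = numeric(), n_bins = integer()))
  ch <- grid$chrom[valid]
  run_id <- cumsum(c(1, diff(cn[valid]) != 0 | ch[-1] != ch[-length(ch)]))
  segs <- lapply(split(valid, run_id), function(idx) {
    data.frame(chrom = grid$chrom[idx[1]],
               start = grid$start[idx[1]],
               end = grid$end[idx[length(idx)]],
               cn = cn[idx[1]],
               mean_log2 = mean(ratios$log2_ratio[idx]),
               n_bins = length(idx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Estimate a sample's copy number profile
#'
#' Runs [em_fit()] from every (f, phi) initialisation on the grid, selects
#' the solution with the highest penalized log-likelihood, calls the
#' zero-ctDNA rule (best-fit fraction below `f_min`, or non-neutral genome
#' fraction below `min_nonneutral`), and merges the Viterbi path into
#' segments.
#'
#' @param ratios A `normalized_ratios` object.
#' @param grid The `bin_grid`.
#' @param config See [profile_config()].
#' @param counts Optional `bin_counts` for the same sample. When supplied,
#'   candidate solutions are ranked by the count-level negative-binomial
#'   likelihood of their state path, which is free of the slight skew the
#'   log2 transform leaves in bin-level ratios and therefore separates
#'   mirror solutions more reliably; otherwise a Gaussian segment-mean
#'   score is used.
#' @return A `segment_profile`.
#' @export
estimate_profile <- function(ratios, grid, config = profile_config(),
                             counts = NULL) {
  hyper <- list(self_transition = config$self_transition,
                max_iter = config$max_iter, tol = config$tol)
  fits <- list()
  for (phi0 in config$phi_grid)
    for (f0 in config$f_grid) {
      fit <- tryCatch(
        em_fit(ratios, grid, f0, phi0, hyper, config$states),
        error = function(e) NULL)
      if (!is.null(fit)) fits[[length(fits) + 1]] <- fit
    }
  if (length(fits) == 0)
    stop("estimation failed: no EM initialisation converged", call. = FALSE)
  spacing <- vapply(fits, function(s)
    (emission_mean(3, s$f, s$phi) - emission_mean(2, s$f, s$phi)) / s$sd,
    numeric(1))
  resolvable <- spacing >= config$spacing_min_sd
  undetectable <- !any(resolvable)
  if (undetectable) {
    best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  } else {
    fits <- fits[resolvable]
    if (!is.null(counts))
      fits <- lapply(fits, nb_polish, ratios = ratios, grid = grid,
                     counts = counts)
    n_valid <- sum(ratios$valid)
    # Candidate ranking. Three ingredients:
    #  (1) goodness of fit of the state path — scored at count level with
    #      a negative binomial when raw counts are available (free of the
    #      slight skew the log2 transform leaves in bin ratios, which
    #      otherwise biases ranking toward over-dense state grids), else
    #      a Gaussian segment-mean score with a BIC complexity term;
    #  (2) a physical floor term: segments of a model-free segmentation
    #      whose mean lies below the candidate's homozygous-deletion
    #      level are impossible under that candidate (copy number cannot
    #      be negative) and are penalised by their squared excess — this
    #      catches small deletions that the path itself cannot afford to
    #      segment at low tumour fraction;
    #  (3) a small aberration-load term breaking exact mirror ties.
    free_segs <- pcf_segments(ratios, grid)
    pen <- vapply(fits, function(s) {
      gof <- if (!is.null(counts)) {
        idx <- which(!is.na(s$bin_cn))
        mu_st <- emission_mean(s$states, s$f, s$phi)
        e0 <- counts$counts[idx] / 2^ratios$log2_ratio[idx]
        mu_i <- e0 * 2^mu_st[match(s$bin_cn[idx], s$states)]
        nb_ll <- function(log_size)
          nb_loglik_capped(counts$counts[idx], mu_i, exp(log_size))
        stats::optimize(nb_ll, c(log(5), log(1e7)), maximum = TRUE)$objective
      } else {
        segs <- segments_from_path(s$bin_cn, ratios, grid)
        mu <- emission_mean(segs$cn, s$f, s$phi)
        sum(stats::dnorm(segs$mean_log2, mu,
                         s$sd / sqrt(segs$n_bins), log = TRUE)) -
          0.5 * log(n_valid) * nrow(segs)
      }
      # effective bin count from genomic length, so short chromosome-end
      # remainder bins (with far noisier depth) are not over-weighted;
      # per-segment penalties are capped to bound the influence of any
      # single non-Gaussian artefact
      n_eff <- free_segs$length / grid_bin_width(grid)
      floor_level <- emission_mean(min(s$states), s$f, s$phi)
      below <- pmax(0, floor_level - free_segs$mean_log2)
      floor_pen <- sum(pmin(12, 0.5 * (below * sqrt(n_eff) / s$sd)^2))
      # ceiling: broad segments (too wide to be focal amplifications)
      # above the candidate's top state level likewise indicate a wrong
      # absolute scale; narrow high-level amplifications are exempt
      top_level <- emission_mean(max(s$states), s$f, s$phi)
      broad <- free_segs$length > 10e6
      above <- pmax(0, free_segs$mean_log2[broad] - top_level)
      ceil_pen <- sum(pmin(12, 0.5 * (above * sqrt(n_eff[broad]) / s$sd)^2))
      gof - floor_pen - ceil_pen - config$lambda * s$aberration_load
    }, numeric(1))
    best <- fits[[which.max(pen)]]
  }

  if (undetectable || best$f < config$f_min ||
      best$nonneutral_fraction < config$min_nonneutral) {
    cn <- ifelse(ratios$valid, 2L, NA_integer_)
    segs <- segments_from_path(cn, ratios, grid)
    return(new_segment_profile(ratios$sample_id, f = 0, phi = 2,
                               segments = segs, bin_cn = cn,
                               loglik = best$loglik, zero_ctdna = TRUE))
  }
  cn <- best$bin_cn
  segs <- segments_from_path(cn, ratios, grid)
  new_segment_profile(ratios$sample_id, f = best$f, phi = best$phi,
                      segments = segs, bin_cn = cn,
                      loglik = best$loglik, zero_ctdna = FALSE)
}

#' Re-express multiple profiles on a common segment grid
#'
#' Takes the union of all samples' segment boundaries per chromosome and
#' re-expresses every sample's piecewise-constant copy number on the common
#' segments; values are unchanged within original segments, so each
#' sample's length-weighted mean CN is preserved exactly.
#'
#' @param profiles List of `segment_profile` objects sharing one bin grid.
#' @return `list(segments=, cn=, mean_log2=, sample_ids=, f=, phi=)`:
#'   common segment table and per-sample matrices (rows = samples,
#'   columns = common segments; NA where a sample has no covering segment).
#' @export
uniform_resegment <- function(profiles) {
  all_segs <- lapply(profiles, `[[`, "segments")
  chroms <- unique(unlist(lapply(all_segs, `[[`, "chrom")))
  common <- list()
  for (ch in chroms) {
    bp <- sort(unique(unlist(lapply(all_segs, function(s) {
      s <- s[s$chrom == ch, ]
      c(s$start, s$end)
    }))))
    if (length(bp) < 2) next
    common[[ch]] <- data.frame(chrom = ch, start = bp[-length(bp)],
                               end = bp[-1], stringsAsFactors = FALSE)
  }
  segments <- do.call(rbind, common)
  rownames(segments) <- NULL
  n_seg <- nrow(segments)
  n_samp <- length(profiles)
  cn <- matrix(NA_real_, n_samp, n_seg)
  ml <- matrix(NA_real_, n_samp, n_seg)
  mid <- (segments$start + segments$end) / 2
  for (i in seq_len(n_samp)) {
    s <- all_segs[[i]]
    for (j in seq_len(nrow(s))) {
      hit <- segments$chrom == s$chrom[j] & mid >= s$start[j] & mid < s$end[j]
      cn[i, hit] <- s$cn[j]
      ml[i, hit] <- s$mean_log2[j]
    }
  }
  list(segments = segments, cn = cn, mean_log2 = ml,
       sample_ids = vapply(profiles, `[[`, character(1), "sample_id"),
       f = vapply(profiles, `[[`, numeric(1), "f"),
       phi = vapply(profiles, `[[`, numeric(1), "phi"))
}
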