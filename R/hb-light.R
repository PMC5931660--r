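#' Sampler configuration for hierarchical Bayesian fits
#'
#' @param chains number of parallel MCMC chains (default 3).
#' @param iter post-burn-in iterations per chain (default 5000; raise to
#'   the full 100000 x 3 protocol via this argument for final runs).
#' @param burnin burn-in (adaptation + update) iterations discarded per
#'   chain (default 2500).
#' @param thin thinning interval.
#' @param seed integer seed; each chain gets a distinct RNG stream
#'   derived from it.
#' @param individual_effects include individual-level random effects for
#'   the capacity parameters a_max and r_d (default TRUE). Species-level
#'   effects on all four parameters are always present. Quantum yield
#'   and convexity carry no individual level: they are physiologically
#'   conserved within a species and a 12-point curve barely identifies
#'   them per leaf, so their between-leaf variation is absorbed by the
#'   residual. A species with a single individual simply has its
#'   individual effect shrunk onto the species mean.
#' @param group_by \code{NULL} for one pooled population mean per
#'   parameter, or a character vector of species-metadata columns (e.g.
#'   \code{"leaf_habit"}) giving each combination its own top-level mean.
#' @param rhat_threshold Gelman-Rubin threshold above which the fit is
#'   flagged non-converged (default 1.1).
#' @return A list of class \code{"hb_config"}.
#' @export
hb_config <- function(chains = 3, iter = 5000, burnin = 2500, thin = 1,
                      seed = 1L, individual_effects = TRUE, group_by = NULL,
                      rhat_threshold = 1.1) {
  stopifnot(chains >= 1, iter >= 100, burnin >= 0, thin >= 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = as.integer(seed),
                 individual_effects = isTRUE(individual_effects),
                 group_by = group_by, rhat_threshold = rhat_threshold),
            class = "hb_config")
}

# JAGS model for the hierarchical NRH fit. Random effects act on
# log(a_max), log(phi), log(r_d) and logit(theta) so every draw respects
# the physiological bounds; top-level means carry weakly-informative
# truncated-normal priors on the natural scale. Species-level SDs get
# half-normal priors whose scales differ by parameter: apparent quantum
# yield and convexity are physiologically conserved across C3 leaves
# (scale 0.15 on the log/logit deviations), while capacity parameters
# (a_max, r_d) genuinely span wide ranges (scale 0.5). Individual-level
# effects exist for the capacity parameters only; per-leaf phi/theta
# deviations are absorbed by the residual (a 12-point curve barely
# identifies them, and freeing them stalls the Gibbs sampler in the
# near-zero-variance funnel).
hb_nrh_model_string <- function(individual_effects) {
  ind_block <- if (individual_effects) "
  for (j in 1:J) {
    log_amax_i[j] ~ dnorm(log(amax_s[sp[j]]), pow(sd_ind[1], -2))
    amax_i[j] <- exp(log_amax_i[j])
    log_rd_i[j] ~ dnorm(log(rd_s[sp[j]]), pow(sd_ind[2], -2))
    rd_i[j] <- exp(log_rd_i[j])
  }
  for (p in 1:2) {
    sd_ind[p] ~ dnorm(0, prec_sd_ind[p]) T(0,)
  }" else "
  for (j in 1:J) {
    amax_i[j] <- amax_s[sp[j]]
    rd_i[j] <- rd_s[sp[j]]
  }"
  paste0("model {
  for (i in 1:N) {
    b[i] <- phi_s[sp[ind[i]]] * q[i] + amax_i[ind[i]]
    disc[i] <- max(pow(b[i], 2) -
      4 * theta_s[sp[ind[i]]] * phi_s[sp[ind[i]]] * q[i] * amax_i[ind[i]], 0)
    mu[i] <- 2 * phi_s[sp[ind[i]]] * q[i] * amax_i[ind[i]] /
      (b[i] + sqrt(disc[i])) - rd_i[ind[i]]
    y[i] ~ dnorm(mu[i], tau_obs)
  }
", ind_block, "
  for (s in 1:S) {
    log_amax_s[s] ~ dnorm(log(M_amax[g[s]]), pow(sd_sp[1], -2))
    amax_s[s] <- exp(log_amax_s[s])
    log_phi_s[s] ~ dnorm(log(M_phi[g[s]]), pow(sd_sp[2], -2)) T(, -2.0794415)
    phi_s[s] <- exp(log_phi_s[s])
    lgt_theta_s[s] ~ dnorm(logit(M_theta[g[s]]), pow(sd_sp[3], -2))
    theta_s[s] <- ilogit(lgt_theta_s[s])
    log_rd_s[s] ~ dnorm(log(M_rd[g[s]]), pow(sd_sp[4], -2))
    rd_s[s] <- exp(log_rd_s[s])
  }
  for (k in 1:G) {
    M_amax[k] ~ dnorm(10, 0.01) T(0.01, 100)
    M_phi[k] ~ dnorm(0.06, 1111.11) T(1e-04, 0.125)
    M_theta[k] ~ dunif(0.001, 0.999)
    M_rd[k] ~ dnorm(1, 0.25) T(0, 10)
  }
  for (p in 1:4) {
    sd_sp[p] ~ dnorm(0, prec_sd_sp[p]) T(0,)
  }
  sd_obs ~ dnorm(0, 0.25) T(0,)
  tau_obs <- pow(sd_obs, -2)
}")
}

#' Fit the hierarchical Bayesian light-response model
#'
#' Fits the non-rectangular hyperbola to all curves jointly by MCMC
#' (JAGS), with species-level random effects on every parameter and
#' individual-level random effects on the capacity parameters (a_max,
#' r_d; see [hb_config()]). Random effects act on log/logit scales so
#' all draws respect the truncation bounds; top-level means have
#' weakly-informative truncated normal priors (a_max ~ N(10, 10^2) on
#' (0, 100); phi ~ N(0.06, 0.03^2) on (0, 0.125]; theta ~ U(0, 1);
#' r_d ~ N(1, 2^2) on [0, 10); observation SD ~ half-normal(2)).
#'
#' Chains are initialised from per-curve least-squares fits
#' ([fit_curves()]), jittered per chain. Convergence is summarised by the
#' Gelman-Rubin statistic for every monitored parameter; the fit is
#' flagged non-converged if any exceeds the configured threshold.
#'
#' @param observations light-curve table (\code{individual_id},
#'   \code{species_code}, \code{ppfd}, \code{a_net}).
#' @param species_meta data.frame with \code{species_code} and any
#'   grouping columns named in \code{config$group_by} (e.g.
#'   \code{nativity}, \code{leaf_habit}). May be \code{NULL} when no
#'   grouping is requested.
#' @param config an [hb_config()] object.
#' @return An object of class \code{"hb_fit"}: list with
#'   \code{summary} (data.frame: parameter, level, label, mean, ci_low,
#'   ci_high, rhat, ess), \code{draws} (a \pkg{coda} \code{mcmc.list} of
#'   the monitored nodes), \code{species} / \code{groups} lookup tables,
#'   \code{converged}, \code{max_rhat} and \code{meta} (chains,
#'   iterations, burn-in, seed).
#' @export
fit_hierarchical <- function(observations, species_meta = NULL,
                             config = hb_config()) {
  assert_columns(observations, c("individual_id", "species_code", "ppfd",
                                 "a_net"), "light-curve table")
  if (nrow(observations) == 0) stop("no observations", call. = FALSE)
  stopifnot(inherits(config, "hb_config"))

  obs <- observations
  ind_ids <- unique(obs$individual_id)
  sp_of_ind <- obs$species_code[match(ind_ids, obs$individual_id)]
  sp_ids <- unique(sp_of_ind)
  if (!is.null(species_meta)) {
    unknown <- setdiff(sp_ids, species_meta$species_code)
    if (length(unknown))
      stop("observations reference unknown species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }

  # Top-level grouping of species.
  if (is.null(config$group_by)) {
    grp_of_sp <- rep("all", length(sp_ids))
  } else {
    assert_columns(species_meta, c("species_code", config$group_by),
                   "species metadata")
    meta_row <- species_meta[match(sp_ids, species_meta$species_code), , drop = FALSE]
    grp_of_sp <- do.call(paste, c(meta_row[config$group_by], sep = ":"))
  }
  grp_ids <- unique(grp_of_sp)

  jdata <- list(
    N = nrow(obs), J = length(ind_ids), S = length(sp_ids), G = length(grp_ids),
    y = obs$a_net, q = obs$ppfd,
    ind = match(obs$individual_id, ind_ids),
    sp = match(sp_of_ind, sp_ids),
    g = match(grp_of_sp, grp_ids),
    prec_sd_sp = c(4, 1 / 0.15^2, 1 / 0.15^2, 4))
  if (config$individual_effects)
    jdata$prec_sd_ind <- c(4, 4)

  inits <- hb_nrh_inits(obs, ind_ids, sp_of_ind, sp_ids, grp_of_sp, grp_ids,
                        config)
  monitors <- c("M_amax", "M_phi", "M_theta", "M_rd",
                "amax_s", "phi_s", "theta_s", "rd_s",
                "sd_sp", "sd_obs")
  if (config$individual_effects) monitors <- c(monitors, "sd_ind")

  model <- rjags::jags.model(
    textConnection(hb_nrh_model_string(config$individual_effects)),
    data = jdata, inits = inits, n.chains = config$chains, quiet = TRUE)
  if (config$burnin > 0) update(model, config$burnin, progress.bar = "none")
  draws <- rjags::coda.samples(model, monitors, n.iter = config$iter,
                               thin = config$thin, progress.bar = "none")

  summ <- summarize_mcmc(draws)
  summ$level <- hb_level_of(summ$parameter)
  summ$label <- hb_label_of(summ$parameter, sp_ids, grp_ids)
  converged <- all(is.finite(summ$rhat)) && max(summ$rhat) <= config$rhat_threshold

  structure(list(
    summary = summ[, c("parameter", "level", "label", "mean", "ci_low",
                       "ci_high", "rhat", "ess")],
    draws = draws,
    species = data.frame(species_code = sp_ids, group = grp_of_sp,
                         stringsAsFactors = FALSE),
    groups = grp_ids,
    converged = converged,
    max_rhat = max(summ$rhat),
    meta = list(chains = config$chains, iter = config$iter,
                burnin = config$burnin, thin = config$thin,
                seed = config$seed,
                individual_effects = config$individual_effects,
                group_by = config$group_by)),
    class = "hb_fit")
}

# Chain inits from per-curve least squares, pooled to species level.
hb_nrh_inits <- function(obs, ind_ids, sp_of_ind, sp_ids, grp_of_sp, grp_ids,
                         config) {
  fits <- suppressWarnings(fit_curves(obs))
  fits <- fits[match(ind_ids, fits$individual_id), ]
  fill <- function(x, default) ifelse(is.finite(x), x, default)
  amax_j <- pmin(pmax(fill(fits$a_max, 10), 0.05), 95)
  phi_j <- pmin(pmax(fill(fits$phi, 0.06), 0.002), 0.12)
  theta_j <- pmin(pmax(fill(fits$theta, 0.7), 0.02), 0.98)
  rd_j <- pmin(pmax(fill(fits$r_d, 0.8), 0.01), 9.5)
  sp_mean <- function(x) {
    m <- tapply(x, sp_of_ind, function(v) exp(mean(log(v))))
    as.numeric(m[sp_ids])
  }
  amax_s <- sp_mean(amax_j); phi_s <- sp_mean(phi_j)
  theta_s <- pmin(pmax(sp_mean(theta_j), 0.02), 0.98); rd_s <- sp_mean(rd_j)
  grp_mean <- function(x) {
    m <- tapply(x, grp_of_sp, function(v) exp(mean(log(v))))
    as.numeric(m[grp_ids])
  }
  sd_sp0 <- 0.2
  sd_ind0 <- 0.1
  lapply(seq_len(config$chains), function(ch) {
    set.seed((config$seed %% 100000L) * 1000L + ch)
    jit <- function(x, sd) x * exp(stats::rnorm(length(x), 0, sd))
    M_amax <- pmin(pmax(jit(grp_mean(amax_s), 0.05), 0.05), 95)
    M_phi <- pmin(pmax(jit(grp_mean(phi_s), 0.03), 0.002), 0.12)
    M_theta <- pmin(pmax(grp_mean(theta_s), 0.05), 0.95)
    M_rd <- pmin(pmax(jit(grp_mean(rd_s), 0.05), 0.02), 9)
    gi <- match(grp_of_sp, grp_ids)
    ini <- list(
      M_amax = M_amax, M_phi = M_phi, M_theta = M_theta, M_rd = M_rd,
      log_amax_s = log(pmin(pmax(jit(amax_s, 0.05), 0.05), 95)),
      log_phi_s = log(pmin(pmax(jit(phi_s, 0.02), 0.002), 0.1249)),
      lgt_theta_s = logit(pmin(pmax(theta_s, 0.02), 0.98)),
      log_rd_s = log(pmin(pmax(jit(rd_s, 0.05), 0.02), 9)),
      sd_sp = rep(sd_sp0, 4), sd_obs = 0.5,
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = (config$seed %% 100000L) * 1000L + ch)
    if (config$individual_effects) {
      ini$log_amax_i <- log(amax_j)
      ini$log_rd_i <- log(rd_j)
      ini$sd_ind <- rep(sd_ind0, 2)
    }
    ini
  })
}

# Posterior mean, central 95% interval, Gelman-Rubin and effective size
# for every column of an mcmc.list.
summarize_mcmc <- function(draws) {
  mat <- do.call(rbind, lapply(draws, as.matrix))
  rhat <- if (length(draws) >= 2) {
    gd <- try(coda::gelman.diag(draws, multivariate = FALSE, autoburnin = FALSE),
              silent = TRUE)
    if (inherits(gd, "try-error")) rep(NA_real_, ncol(mat)) else gd$psrf[, 1]
  } else rep(NA_real_, ncol(mat))
  ess <- as.numeric(coda::effectiveSize(draws))
  data.frame(
    parameter = colnames(mat),
    mean = colMeans(mat),
    ci_low = apply(mat, 2, stats::quantile, 0.025),
    ci_high = apply(mat, 2, stats::quantile, 0.975),
    rhat = rhat, ess = ess,
    row.names = NULL, stringsAsFactors = FALSE)
}

hb_level_of <- function(parameter) {
  base <- sub("\\[.*", "", parameter)
  ifelse(base %in% c("M_amax", "M_phi", "M_theta", "M_rd"), "group",
    ifelse(base %in% c("amax_s", "phi_s", "theta_s", "rd_s"), "species",
      "hyper"))
}

hb_label_of <- function(parameter, sp_ids, grp_ids) {
  idx <- suppressWarnings(as.integer(sub(".*\\[(\\d+)\\]", "\\1", parameter)))
  base <- sub("\\[.*", "", parameter)
  lab <- parameter
  is_sp <- base %in% c("amax_s", "phi_s", "theta_s", "rd_s")
  is_gr <- base %in% c("M_amax", "M_phi", "M_theta", "M_rd")
  lab[is_sp] <- sp_ids[idx[is_sp]]
  lab[is_gr] <- grp_ids[ifelse(is.na(idx[is_gr]), 1L, idx[is_gr])]
  lab
}

#' @export
print.hb_fit <- function(x, ...) {
  cat(sprintf(
    "Hierarchical NRH fit: %d species, %d groups; %d chains x %d iterations\n",
    nrow(x$species), length(x$groups), x$meta$chains, x$meta$iter))
  cat(sprintf("max Gelman-Rubin = %.3f (%s)\n", x$max_rhat,
              if (x$converged) "converged" else "NOT CONVERGED"))
  grp <- x$summary[x$summary$level == "group", ]
  print(grp[, c("parameter", "label", "mean", "ci_low", "ci_high", "rhat")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Extract species-level posterior summaries from a hierarchical fit
#'
#' Returns one row per species with the posterior mean and 95% credible
#' interval of each NRH parameter, plus the light compensation point
#' evaluated at the posterior means.
#'
#' @param fit an [fit_hierarchical()] result.
#' @return data.frame with \code{species_code}, \code{group}, and
#'   \code{a_max}, \code{phi}, \code{theta}, \code{r_d} with their
#'   \code{*_lo}/\code{*_hi} bounds, and \code{lcp}.
#' @export
species_posteriors <- function(fit) {
  stopifnot(inherits(fit, "hb_fit"))
  s <- fit$summary[fit$summary$level == "species", ]
  wide <- fit$species
  for (par in c("amax_s", "phi_s", "theta_s", "rd_s")) {
    rows <- s[startsWith(s$parameter, paste0(par, "[")), ]
    rows <- rows[match(wide$species_code, rows$label), ]
    nm <- c(amax_s = "a_max", phi_s = "phi", theta_s = "theta", rd_s = "r_d")[[par]]
    wide[[nm]] <- rows$mean
    wide[[paste0(nm, "_lo")]] <- rows$ci_low
    wide[[paste0(nm, "_hi")]] <- rows$ci_high
  }
  wide$lcp <- mapply(function(a, p, t, r)
    if (r < a) lcp_of(nrh_params(a, p, t, r)) else NA_real_,
    wide$a_max, wide$phi, wide$theta, wide$r_d)
  wide
}

#' Posterior contrast between two top-level groups
#'
#' Computes the posterior distribution of the difference (group a minus
#' group b) of a top-level parameter mean from a grouped hierarchical
#' fit, e.g. the deciduous-evergreen difference in A_max.
#'
#' @param fit an [fit_hierarchical()] result fitted with
#'   \code{group_by} set.
#' @param parameter one of \code{"a_max"}, \code{"phi"}, \code{"theta"},
#'   \code{"r_d"}.
#' @param a,b group labels (as in \code{fit$groups}).
#' @return list with \code{mean}, \code{ci_low}, \code{ci_high} and
#'   \code{excludes_zero}.
#' @export
group_difference <- function(fit, parameter = "a_max", a, b) {
  stopifnot(inherits(fit, "hb_fit"))
  node <- c(a_max = "M_amax", phi = "M_phi", theta = "M_theta",
            r_d = "M_rd")[[parameter]]
  ia <- match(a, fit$groups)
  ib <- match(b, fit$groups)
  if (is.na(ia) || is.na(ib))
    stop("unknown group label; available: ",
         paste(fit$groups, collapse = ", "), call. = FALSE)
  mat <- do.call(rbind, lapply(fit$draws, as.matrix))
  col_of <- function(i) if (length(fit$groups) == 1) node else
    sprintf("%s[%d]", node, i)
  d <- mat[, col_of(ia)] - mat[, col_of(ib)]
  ci <- unname(stats::quantile(d, c(0.025, 0.975)))
  list(mean = mean(d), ci_low = ci[1], ci_high = ci[2],
       excludes_zero = significance_from_ci(ci[1], ci[2]))
}
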