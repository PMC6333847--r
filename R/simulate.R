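#' Default set of implanted longitudinal connections
#'
#' Five (node pair, metric) triples on which the simulator concentrates
#' the disease-related longitudinal change: two streamline-count
#' connections (right red nucleus to left internal pallidum; left putamen
#' to left thalamus) and three FA connections (inter-hemispheric external
#' pallidum; left putamen to left external pallidum; right caudate to
#' right thalamus).  These involve the pallidal direct/indirect pathways
#' and thalamic relays where degeneration-driven change is expected.
#'
#' @return Data frame with columns `node_a`, `node_b`, `metric`.
#' @export
default_affected_edges <- function() {
  data.frame(
    node_a = c("R-RN", "L-PUT", "R-GPe", "L-PUT", "R-CAUD"),
    node_b = c("L-GPi", "L-THAL", "L-GPe", "L-GPe", "R-THAL"),
    metric = c("streamline_count", "streamline_count",
               "mean_fa", "mean_fa", "mean_fa"),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic longitudinal cohort.  Defaults mirror the
#' study design: 30 Controls, 21 de novo Parkinson's disease (PD) and 16
#' prodromal (PROD) subjects, with 11/16 of the PROD group drawn from the
#' PD-like change model.
#'
#' @param n_cnt,n_pd,n_prod Group sizes (each >= 2).
#' @param affected_edges Data frame of (node_a, node_b, metric) triples
#'   carrying the implanted longitudinal effect; default
#'   [default_affected_edges()].
#' @param effect_size Size of the implanted mean longitudinal change on
#'   affected edges, in units of the within-group change SD (>= 0; 0
#'   disables the effect entirely).
#' @param prod_mixture Probability that a PROD subject follows the
#'   PD-like change model (default 11/16).
#' @param prod_attenuation Multiplier applied to `effect_size` for
#'   PD-like PROD subjects (default 0.8: prodromal degeneration is
#'   subtler than manifest disease).
#' @param rho Within-subject baseline/follow-up correlation of edge
#'   values, on the latent scale (0 <= rho < 1; default 0.9, i.e. most
#'   edge variance is stable anatomy, change is a small perturbation).
#' @param count_mean_log,count_mean_sdlog Log-normal hyper-parameters of
#'   the pair-specific expected streamline counts (median ~ 50).
#' @param count_size Negative-binomial dispersion of counts around the
#'   pair mean.
#' @param fa_mu,fa_sd Centre and subject-level jitter SD of mean FA.
#' @param md_mu,md_sd Centre (mm^2/s) and jitter SD of mean MD.
#' @param effect_var_inflation Multiplier on the change-noise SD of
#'   affected edges in PD-like subjects (variance inflation of the
#'   diseased change process).
#' @param male_frac Named vector of male fractions per group; defaults
#'   follow the cohort table (19/30, 17/21, 14/16 - the prodromal group
#'   is heavily male, as REM sleep behaviour disorder is).
#' @param seed Master seed (integer).
#' @return An object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(n_cnt = 30L, n_pd = 21L, n_prod = 16L,
                              affected_edges = default_affected_edges(),
                              effect_size = 3,
                              prod_mixture = 11 / 16,
                              prod_attenuation = 0.8,
                              rho = 0.9,
                              count_mean_log = log(50),
                              count_mean_sdlog = 0.8,
                              count_size = 10,
                              fa_mu = 0.45, fa_sd = 0.04,
                              md_mu = 0.7e-3, md_sd = 0.35e-4,
                              effect_var_inflation = 1.5,
                              male_frac = c(CNT = 19 / 30, PD = 17 / 21,
                                            PROD = 14 / 16),
                              seed = 1L) {
  cfg <- list(n_cnt = as.integer(n_cnt), n_pd = as.integer(n_pd),
              n_prod = as.integer(n_prod),
              affected_edges = affected_edges,
              effect_size = effect_size, prod_mixture = prod_mixture,
              prod_attenuation = prod_attenuation, rho = rho,
              count_mean_log = count_mean_log,
              count_mean_sdlog = count_mean_sdlog,
              count_size = count_size,
              fa_mu = fa_mu, fa_sd = fa_sd, md_mu = md_mu, md_sd = md_sd,
              effect_var_inflation = effect_var_inflation,
              male_frac = male_frac, seed = as.integer(seed))
  stopifnot(cfg$n_cnt >= 2, cfg$n_pd >= 2, cfg$n_prod >= 0,
            cfg$effect_size >= 0,
            cfg$prod_mixture >= 0, cfg$prod_mixture <= 1,
            cfg$rho >= 0, cfg$rho < 1,
            cfg$count_size > 0, cfg$fa_sd > 0, cfg$md_sd > 0,
            is.data.frame(cfg$affected_edges),
            all(c("node_a", "node_b", "metric") %in%
                  names(cfg$affected_edges)))
  if (!all(cfg$affected_edges$metric %in% connectome_metrics()))
    stop("unknown metric in affected_edges")
  labels <- atlas_nodes()$label
  if (!all(c(cfg$affected_edges$node_a, cfg$affected_edges$node_b) %in%
             labels))
    stop("unknown node label in affected_edges")
  class(cfg) <- "sim_config"
  cfg
}

# Derive independent sub-seeds for the structure / noise / clinical RNG
# streams from the master seed (kept below 2^31).
derive_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 3L)
  names(s) <- c("structure", "noise", "clinical")
  s
}

# Map affected (pair, metric) triples to feature indices 1..360
affected_feature_idx <- function(affected_edges) {
  map <- edge_feature_map()
  key <- function(a, b, m) {
    swap <- a > b
    paste(ifelse(swap, b, a), ifelse(swap, a, b), m, sep = "|")
  }
  mk <- key(map$node_a, map$node_b, map$metric)
  ak <- key(affected_edges$node_a, affected_edges$node_b,
            affected_edges$metric)
  idx <- match(ak, mk)
  if (anyNA(idx)) stop("affected edge not found in edge_feature_map")
  idx
}

#' Simulate a longitudinal connectome cohort
#'
#' Generates baseline and follow-up connectomes for three groups (CNT,
#' PD, PROD) with known ground truth.  Edge-level generative model, per
#' metric:
#' \itemize{
#'   \item streamline counts: pair-specific expected counts are drawn
#'     once per cohort from a log-normal (median ~ 50); baseline counts
#'     are negative-binomial around the pair mean; follow-up counts are a
#'     correlated redraw (correlation `rho` on the latent Gaussian scale)
#'     rounded and floored at zero.
#'   \item mean FA: pair-specific means near `fa_mu`, subject jitter SD
#'     `fa_sd`, clamped to \[0, 1\]; follow-up correlated with baseline.
#'   \item mean MD: identical construction around `md_mu`, floored at a
#'     small positive value.
#' }
#' Cells with zero streamline count are forced to zero FA/MD (no
#' streamlines, no averaged tensor metric).  Groups differ only in the
#' longitudinal change: PD subjects (and PD-like PROD subjects, chosen
#' with probability `prod_mixture`) receive an additional signed shift of
#' `effect_size` change-SD units, with inflated change variance, on the
#' `affected_edges`; Controls and control-like PROD subjects receive
#' noise-only change.  Baseline levels carry no group information by
#' design, so only progression is informative.
#'
#' @param config A [simulation_config()] object.
#' @return An object of class `cohort`: list with `features` (n x 360
#'   matrix), `manifest` (subject_id, group, age, gender,
#'   days_between_scans), `truth` (affected feature indices and latent
#'   class per subject), `connectomes` (per subject: list of 6 matrices),
#'   and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed)
  pairs <- edge_pairs()
  n_edge <- nrow(pairs)

  # -- cohort structure stream: pair means, group layout, covariates,
  #    latent classes
  set.seed(seeds[["structure"]])
  count_mu <- exp(rnorm(n_edge, config$count_mean_log,
                        config$count_mean_sdlog))
  fa_mu_pair <- pmin(pmax(rnorm(n_edge, config$fa_mu, 0.05), 0.05), 0.9)
  md_mu_pair <- config$md_mu * exp(rnorm(n_edge, 0, 0.08))

  groups <- rep(c("CNT", "PD", "PROD"),
                c(config$n_cnt, config$n_pd, config$n_prod))
  n <- length(groups)
  subject_id <- sprintf("S%03d", seq_len(n))
  age <- pmin(pmax(rnorm(n, 66, 5), 45), 85)
  gender <- ifelse(runif(n) < unname(config$male_frac[groups]), "M", "F")
  days <- round(pmin(pmax(rnorm(n, 400, 80), 200), 700))
  latent <- ifelse(groups == "PD", "pd_like",
                   ifelse(groups == "CNT", "control_like", NA))
  latent[groups == "PROD"] <-
    ifelse(runif(sum(groups == "PROD")) < config$prod_mixture,
           "pd_like", "control_like")

  aff_feat <- affected_feature_idx(config$affected_edges)
  aff_by_metric <- lapply(seq_along(connectome_metrics()), function(m) {
    f <- aff_feat[aff_feat > (m - 1L) * 120L & aff_feat <= m * 120L]
    f - (m - 1L) * 120L
  })
  names(aff_by_metric) <- connectome_metrics()

  # per-edge SDs on the sampling scale
  count_sd <- sqrt(count_mu + count_mu^2 / config$count_size)
  sd_of <- list(streamline_count = count_sd,
                mean_fa = rep(config$fa_sd, n_edge),
                mean_md = rep(config$md_sd, n_edge))
  mu_of <- list(streamline_count = count_mu,
                mean_fa = fa_mu_pair,
                mean_md = md_mu_pair)
  # SD of the noise-only longitudinal change implied by correlation rho
  rho <- config$rho
  change_sd <- lapply(sd_of, function(s) s * sqrt(2 * (1 - rho)))

  clamp <- function(x, metric) {
    switch(metric,
           streamline_count = pmax(round(x), 0),
           mean_fa = pmin(pmax(x, 0), 1),
           mean_md = pmax(x, 1e-6))
  }

  # -- noise stream: per-subject edge values
  set.seed(seeds[["noise"]])
  subjects <- vector("list", n)
  for (s in seq_len(n)) {
    diseased <- latent[s] == "pd_like"
    eff <- if (groups[s] == "PROD") {
      config$effect_size * config$prod_attenuation
    } else config$effect_size
    conns <- list()
    for (metric in connectome_metrics()) {
      mu <- mu_of[[metric]]; sdv <- sd_of[[metric]]
      if (metric == "streamline_count") {
        base_raw <- as.numeric(rnbinom(n_edge, mu = mu,
                                       size = config$count_size))
      } else {
        base_raw <- rnorm(n_edge, mu, sdv)
      }
      noise_sd <- sqrt(1 - rho^2) * sdv
      fu_raw <- mu + rho * (base_raw - mu) + rnorm(n_edge, 0, noise_sd)
      if (diseased && eff > 0) {
        ae <- aff_by_metric[[metric]]
        if (length(ae)) {
          sign <- sample(c(-1, 1), length(ae), replace = TRUE)
          shift <- eff * change_sd[[metric]][ae] *
            runif(length(ae), 0.75, 1.25)
          extra_sd <- (config$effect_var_inflation - 1) *
            change_sd[[metric]][ae]
          fu_raw[ae] <- fu_raw[ae] + sign * shift +
            rnorm(length(ae), 0, extra_sd)
        }
      }
      base <- clamp(base_raw, metric)
      fu <- clamp(fu_raw, metric)
      conns[[paste0("baseline.", metric)]] <- base
      conns[[paste0("followup.", metric)]] <- fu
    }
    # zero streamlines => zero FA/MD at that timepoint
    for (tp in c("baseline", "followup")) {
      z <- conns[[paste0(tp, ".streamline_count")]] == 0
      conns[[paste0(tp, ".mean_fa")]][z] <- 0
      conns[[paste0(tp, ".mean_md")]][z] <- 0
    }
    subjects[[s]] <- conns
  }

  # assemble feature matrix and matrices
  map <- edge_feature_map()
  features <- matrix(0, n, 360L,
                     dimnames = list(subject_id, map$name))
  connectomes <- vector("list", n)
  names(connectomes) <- subject_id
  for (s in seq_len(n)) {
    conns <- subjects[[s]]
    feats <- unlist(lapply(connectome_metrics(), function(metric) {
      abs(conns[[paste0("followup.", metric)]] -
            conns[[paste0("baseline.", metric)]])
    }), use.names = FALSE)
    features[s, ] <- feats
    connectomes[[s]] <- lapply(conns, edge_vector_to_matrix)
  }

  manifest <- data.frame(subject_id = subject_id, group = groups,
                         age = age, gender = gender,
                         days_between_scans = days,
                         stringsAsFactors = FALSE)
  structure(
    list(features = features,
         manifest = manifest,
         truth = list(affected_features = aff_feat,
                      affected_edges = config$affected_edges,
                      latent_class = stats::setNames(latent, subject_id)),
         connectomes = connectomes,
         config = config),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$manifest$group)
  cat("<cohort> ", nrow(x$features), " subjects (",
      paste(names(tab), tab, sep = "=", collapse = ", "),
      "), 360 longitudinal features\n", sep = "")
  invisible(x)
}

#' Simulate clinical rating-scale trajectories
#'
#' Generates UPDRS-III, Hoehn & Yahr (H&Y), MoCA and SDM values at
#' baseline, year-1 and year-1.5 visits, consistent with each subject's
#' latent class.  Baseline magnitudes follow the cohort table of the
#' emulated study (Controls: UPDRS-III ~ 1, H&Y 0, MoCA ~ 28, SDM ~ 43;
#' PD: UPDRS-III ~ 21, H&Y ~ 1.5; PROD baselines intermediate-low).
#' PD-like subjects drift upward on the motor scales over follow-up;
#' control-like subjects stay near their baseline.  MoCA/SDM decline
#' mildly in PD-like subjects.  MoCA and SDM are reported as missing at
#' the 1.5-year visit (not collected at that visit in the emulated
#' protocol).
#'
#' @param config A [simulation_config()].
#' @param cohort The [simulate_cohort()] output for the same config.
#' @return Data frame with columns `subject_id`, `group`, `visit`
#'   (0, 1, 1.5 years), `updrs3`, `hy`, `moca`, `sdm`.
#' @export
simulate_clinical <- function(config, cohort) {
  stopifnot(inherits(config, "sim_config"), inherits(cohort, "cohort"))
  seeds <- derive_seeds(config$seed)
  set.seed(seeds[["clinical"]])
  man <- cohort$manifest
  latent <- cohort$truth$latent_class[man$subject_id]
  visits <- c(0, 1, 1.5)
  out <- vector("list", nrow(man))
  half_round <- function(x) round(x * 2) / 2
  for (s in seq_len(nrow(man))) {
    g <- man$group[s]; pd_like <- latent[s] == "pd_like"
    if (g == "PD") {
      updrs0 <- max(0, round(rnorm(1, 21, 8)))
      hy0 <- half_round(min(max(rnorm(1, 1.5, 0.5), 1), 2.5))
      drift_u <- 3; drift_h <- 0.25
    } else if (pd_like) {            # PD-like prodromal
      updrs0 <- max(0, round(rnorm(1, 4, 3)))
      hy0 <- half_round(max(rnorm(1, 0.1, 0.25), 0))
      drift_u <- 3.5; drift_h <- 0.35
    } else {                         # controls and control-like PROD
      updrs0 <- rpois(1, 1)
      hy0 <- 0
      drift_u <- 0; drift_h <- 0
    }
    moca0 <- min(max(round(rnorm(1, if (g == "PD") 26.3 else 27.8, 1.5)),
                     15), 30)
    sdm0 <- max(0, round(rnorm(1, if (g == "CNT") 43 else 36, 7)))
    updrs <- pmax(0, round(updrs0 + drift_u * visits +
                             rnorm(3, 0, 1.5 + 2 * pd_like)))
    hy <- pmax(0, half_round(hy0 + drift_h * visits +
                               rnorm(3, 0, 0.1 + 0.2 * pd_like)))
    moca <- pmin(pmax(round(moca0 - (if (pd_like) 0.8 else 0.3) * visits +
                              rnorm(3, 0, 1)), 0), 30)
    sdm <- pmax(0, round(sdm0 - (if (pd_like) 1.5 else 0.3) * visits +
                           rnorm(3, 0, 2)))
    moca[visits == 1.5] <- NA_integer_
    sdm[visits == 1.5] <- NA_integer_
    out[[s]] <- data.frame(subject_id = man$subject_id[s], group = g,
                           visit = visits, updrs3 = updrs, hy = hy,
                           moca = moca, sdm = sdm,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
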