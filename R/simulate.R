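#' @title Synthetic genotype-phenotype-environment simulator
#' @description Generates every input the pipeline consumes, so the whole
#'   package is testable without external data: biallelic dosage matrices at
#'   chosen minor-allele frequencies (outbred or fully homozygous inbred
#'   panels) with GATK-style INFO annotations, additive (+ dominance) traits
#'   at a controlled narrow-sense heritability, factorial inbred cross
#'   designs with derived F1 genotypes and traits, and multi-environment
#'   daily weather series whose linear combination drives environment-
#'   specific trait shifts. All generators are pure functions of
#'   (config, seed).
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' @param n samples; `L` loci; `maf` minor-allele-frequency range;
#'   `n_qtl` causal loci; `effect_sd` additive-effect scale; `h2` target
#'   narrow-sense heritability in (0, 1]; `dominance` dominance-to-additive
#'   effect-scale ratio; `missing_rate` fraction of dosage entries masked;
#'   `bad_info_frac` fraction of loci whose INFO metrics violate each hard
#'   filter bound; `n_env` environments; `env_sd` across-environment trait
#'   shift scale (in units of the trait); `env_days` days of daily weather
#'   per environment; `seed` master seed.
#' @param L,maf,n_qtl,effect_sd,h2,dominance,missing_rate,bad_info_frac,n_env,env_sd,env_days,seed see above.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n = 2000, L = 500, maf = c(0.05, 0.5), n_qtl = 50,
                       effect_sd = 1, h2 = 0.9, dominance = 0,
                       missing_rate = 0, bad_info_frac = 0, n_env = 5,
                       env_sd = 1, env_days = 60, seed = 1L) {
  stopifnot(maf[1] > 0, maf[2] <= 0.5, n_qtl <= L, h2 > 0, h2 <= 1)
  structure(list(n = n, L = L, maf = maf, n_qtl = n_qtl,
                 effect_sd = effect_sd, h2 = h2, dominance = dominance,
                 missing_rate = missing_rate, bad_info_frac = bad_info_frac,
                 n_env = n_env, env_sd = env_sd, env_days = env_days,
                 seed = as.integer(seed)), class = "sim_config")
}

#' Simulate a biallelic genotype panel with variant annotations
#'
#' Loci are independent; outbred dosages are Binomial(2, p), inbred panels
#' draw dosage 0 or 2 (no heterozygotes). INFO metrics are drawn well
#' inside the passing range; with `bad_info_frac > 0` that fraction of loci
#' (per metric, disjointly sampled) violates each hard-filter bound.
#'
#' @param cfg a [sim_config()].
#' @param inbred simulate a fully homozygous panel.
#' @param ids optional sample ids (default `s0001`...).
#' @return list with `genotypes` (dosage matrix, `NA` where masked),
#'   `variants` (variant table with synthetic INFO metrics) and `maf`
#'   (generating allele frequencies).
#' @export
simulate_genotypes <- function(cfg, inbred = FALSE, ids = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n; L <- cfg$L
  p <- stats::runif(L, cfg$maf[1], cfg$maf[2])
  G <- if (inbred) {
    2L * matrix(stats::rbinom(n * L, 1, rep(p, each = n)), n, L)
  } else {
    matrix(stats::rbinom(n * L, 2, rep(p, each = n)), n, L)
  }
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(n * L) < cfg$missing_rate, n, L)
    G[mask] <- NA_integer_
  }
  ids <- ids %||% sprintf("s%04d", seq_len(n))
  rownames(G) <- ids
  pos <- sort(sample.int(L * 200L, L))
  ref <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  vt <- data.frame(chrom = "1", pos = pos, ref = ref, alt = unname(alt),
                   qual = stats::runif(L, 100, 1000),
                   QD = stats::runif(L, 15, 35),
                   FS = stats::runif(L, 0, 10),
                   MQ = stats::runif(L, 50, 60),
                   SOR = stats::runif(L, 0.5, 2),
                   MQRankSum = stats::runif(L, -2, 2),
                   stringsAsFactors = FALSE)
  if (cfg$bad_info_frac > 0) {
    nbad <- max(1L, round(cfg$bad_info_frac * L))
    pool <- sample.int(L)           # disjoint violators per metric
    take <- function(i) pool[((i - 1) * nbad + 1):min(i * nbad, L)]
    vt$QD[take(1)] <- stats::runif(length(take(1)), 0, 1.9)
    vt$FS[take(2)] <- stats::runif(length(take(2)), 60.1, 200)
    vt$MQ[take(3)] <- stats::runif(length(take(3)), 10, 39.9)
    vt$SOR[take(4)] <- stats::runif(length(take(4)), 3.1, 9)
    vt$MQRankSum[take(5)] <- stats::runif(length(take(5)), -30, -12.6)
  }
  vt$missing_rate <- colMeans(is.na(G))
  colnames(G) <- locus_key(vt$chrom, vt$pos, vt$ref, vt$alt)
  list(genotypes = G, variants = vt, maf = p)
}

# Additive(+dominance) genetic values for a dosage matrix under a fixed
# effect set.
genetic_values <- function(G, effects) {
  g <- as.vector(G[, effects$qtl, drop = FALSE] %*% effects$beta)
  if (!is.null(effects$dom) && any(effects$dom != 0))
    g <- g + as.vector((G[, effects$qtl, drop = FALSE] == 1L) %*% effects$dom)
  g
}

draw_effects <- function(cfg) {
  qtl <- sample.int(cfg$L, cfg$n_qtl)
  beta <- stats::rnorm(cfg$n_qtl, 0, cfg$effect_sd)
  dom <- if (cfg$dominance > 0)
    stats::rnorm(cfg$n_qtl, 0, cfg$dominance * cfg$effect_sd) else
      rep(0, cfg$n_qtl)
  list(qtl = qtl, beta = beta, dom = dom)
}

# Noise orthogonalized against the genetic values and scaled so the sample
# variance ratio Var(genetic)/Var(y) equals h2 exactly.
add_noise_to_h2 <- function(g, h2) {
  if (h2 >= 1) return(g)
  vg <- stats::var(g)
  if (vg < 1e-12) abort_stage("synthetic_data", "genetic variance is zero; cannot set h2")
  eps <- stats::rnorm(length(g))
  eps <- stats::resid(stats::lm(eps ~ g))
  eps <- eps / stats::sd(eps) * sqrt(vg * (1 - h2) / h2)
  g + eps
}

#' Simulate an additive(+dominance) trait at controlled heritability
#'
#' `y = sum_q beta_q g_q (+ dominance deviations) + eps`, with `eps`
#' orthogonalized against the genetic values and scaled so that the realized
#' sample ratio Var(genetic)/Var(y) equals `h2` exactly. With `h2 = 1` the
#' trait is the genetic value.
#'
#' @param G imputed dosage matrix.
#' @param cfg a [sim_config()].
#' @param effects optional pre-drawn effect set (to score a second
#'   population under the same genetic model).
#' @return list with `phenotypes` (sample, value), `effects` (qtl indices,
#'   additive and dominance effects) and `genetic` (true genetic values).
#' @export
simulate_trait <- function(G, cfg, effects = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  effects <- effects %||% draw_effects(cfg)
  g <- genetic_values(G, effects)
  y <- add_noise_to_h2(g, cfg$h2)
  list(phenotypes = data.frame(sample = rownames(G), value = y,
                               stringsAsFactors = FALSE),
       effects = effects, genetic = stats::setNames(g, rownames(G)))
}

#' Simulate multi-environment daily weather and trait shifts
#'
#' Each environment gets `env_days` days of the 11 weather variables
#' (seasonal sinusoid + environment offset + day noise). The per-environment
#' trait shift is an exact linear function of the mean maximum temperature,
#' solar radiation and precipitation, centred and scaled across environments
#' to `env_sd` — so a model that reads the weather has real signal to learn,
#' and a regression of shifts on the generating variables is noise-free.
#'
#' @param cfg a [sim_config()].
#' @return list with `weather` (data.frame env, date, 11 variables),
#'   `shifts` (named per-environment trait shift) and `coefficients` (the
#'   generating linear map on the per-environment variable means).
#' @export
simulate_environments <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  envs <- sprintf("E%02d", seq_len(cfg$n_env))
  days <- seq_len(cfg$env_days)
  dates <- format(as.Date("2015-05-01") + days - 1)
  base_mean <- c(tempmax = 28, tempmin = 16, humidity = 65, precip = 3,
                 windspeed = 12, sealevelpressure = 1013, cloudcover = 40,
                 solarradiation = 220, solarenergy = 19, uvindex = 7,
                 sunhours = 10)
  base_amp <- c(5, 4, 15, 3, 4, 6, 25, 60, 5, 2, 3)
  rows <- lapply(seq_along(envs), function(i) {
    off <- stats::rnorm(11, 0, base_amp / 2)
    phase <- stats::runif(11, 0, 2 * pi)
    M <- sapply(seq_len(11), function(v) {
      base_mean[v] + off[v] +
        base_amp[v] * 0.3 * sin(2 * pi * days / 365 + phase[v]) +
        stats::rnorm(length(days), 0, base_amp[v] * 0.15)
    })
    colnames(M) <- env_var_names
    data.frame(env = envs[i], date = dates, M, stringsAsFactors = FALSE,
               row.names = NULL)
  })
  weather <- do.call(rbind, rows)
  means <- rowsum(as.matrix(weather[env_var_names]), weather$env) /
    cfg$env_days
  coef <- stats::setNames(rep(0, 11), env_var_names)
  coef[c("tempmax", "solarradiation", "precip")] <- c(0.6, 0.02, -0.4)
  raw <- as.vector(means %*% coef)
  s <- stats::sd(raw)
  scale <- if (s < 1e-12) 0 else cfg$env_sd / s
  shifts <- stats::setNames((raw - mean(raw)) * scale, rownames(means))
  list(weather = weather, shifts = shifts,
       coefficients = list(raw = coef, scale = scale,
                           center = mean(raw)))
}

#' Simulate a multi-environment trait
#'
#' Every sample is phenotyped in every environment:
#' `y_ie = g_i + shift_e + eps_ie`, with within-environment noise scaled to
#' the target `h2` against the genetic variance.
#'
#' @param G imputed dosage matrix.
#' @param cfg a [sim_config()].
#' @return list with `phenotypes` (sample, value, env), `weather`,
#'   `shifts`, `effects` and `genetic`.
#' @export
simulate_env_trait <- function(G, cfg) {
  env <- simulate_environments(cfg)
  set.seed(cfg$seed + 3L)
  effects <- draw_effects(cfg)
  g <- genetic_values(G, effects)
  vg <- stats::var(g)
  sde <- if (cfg$h2 >= 1) 0 else sqrt(vg * (1 - cfg$h2) / cfg$h2)
  # cfg$env_sd is in units of the genetic SD: rescale the raw shifts
  # (drawn with sd cfg$env_sd) to sd cfg$env_sd * sd(g)
  shifts <- env$shifts / max(cfg$env_sd, 1e-12) * (cfg$env_sd * sqrt(vg))
  recs <- do.call(rbind, lapply(names(shifts), function(e) {
    data.frame(sample = rownames(G),
               value = g + shifts[[e]] +
                 stats::rnorm(length(g), 0, sde),
               env = e, stringsAsFactors = FALSE)
  }))
  list(phenotypes = recs, weather = env$weather, shifts = shifts,
       effects = effects, genetic = stats::setNames(g, rownames(G)))
}

#' Simulate a factorial inbred cross design with F1 genotypes and traits
#'
#' Mirrors an NCII mating design: `n_female + n_male` homozygous inbred
#' lines, every female x male F1 derived by the expected-dosage cross rule,
#' and F1 traits scored under one shared additive effect model at the
#' config's heritability. The ground-truth ranking of crosses by true F1
#' genetic value is returned for oracle tests.
#'
#' @param n_female,n_male numbers of female and male inbred parents.
#' @param cfg a [sim_config()]; `cfg$n` is ignored (panel size is
#'   `n_female + n_male`).
#' @return list with `panel` (inbred dosage matrix), `females`, `males`,
#'   `plan` (all pairs), `f1_genotypes`, `f1_phenotypes`, `genetic`
#'   (true F1 genetic values) and `truth` (best pair and full order).
#' @export
simulate_cross_population <- function(n_female, n_male, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  panel_cfg <- cfg
  panel_cfg$n <- n_female + n_male
  ids <- c(sprintf("F%03d", seq_len(n_female)),
           sprintf("M%03d", seq_len(n_male)))
  sim <- simulate_genotypes(panel_cfg, inbred = TRUE, ids = ids)
  females <- ids[seq_len(n_female)]
  males <- ids[n_female + seq_len(n_male)]
  plan <- cross_plan(females, males)
  f1 <- f1_genotypes(sim$genotypes, plan)
  set.seed(cfg$seed + 4L)
  effects <- draw_effects(cfg)
  g <- genetic_values(f1, effects)
  y <- add_noise_to_h2(g, cfg$h2)
  ord <- order(-g, plan$female, plan$male)
  list(panel = sim$genotypes, variants = sim$variants,
       females = females, males = males, plan = plan,
       f1_genotypes = f1,
       f1_phenotypes = data.frame(sample = rownames(f1), value = y,
                                  stringsAsFactors = FALSE),
       genetic = stats::setNames(g, rownames(f1)), effects = effects,
       truth = list(best = plan[ord[1], , drop = FALSE], order = ord))
}
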