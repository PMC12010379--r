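#' Expected F1 genotype of two inbred parents
#'
#' Per locus the F1 dosage is `(pa + pb) / 2`: homozygous-ref x
#' homozygous-alt gives a heterozygote, identical parents reproduce
#' themselves. Heterozygous parent loci (non-inbred input) trigger a
#' warning; the expected-dosage rule is still applied.
#'
#' @param pa,pb parental dosage vectors over aligned loci.
#' @return numeric F1 dosage vector.
#' @export
make_f1_genotype <- function(pa, pb) {
  if (length(pa) != length(pb))
    abort_stage("breeding_workflows", "parent dosage vectors differ in length")
  if (any(pa == 1L, na.rm = TRUE) || any(pb == 1L, na.rm = TRUE))
    warning("make_f1_genotype: heterozygous parent locus; expected-dosage rule applied")
  (pa + pb) / 2
}

#' Enumerate a factorial cross plan
#'
#' @param females,males parent id vectors.
#' @return data.frame of all (female, male) pairs, female-major order.
#' @export
cross_plan <- function(females, males) {
  plan <- expand.grid(male = males, female = females,
                      stringsAsFactors = FALSE)[, c("female", "male")]
  rownames(plan) <- NULL
  if (anyDuplicated(plan))
    abort_stage("breeding_workflows", "duplicate cross in plan")
  plan
}

#' Construct all F1 genotypes for a cross plan
#'
#' @param panel inbred dosage matrix with parent ids as rownames.
#' @param plan data.frame with `female`, `male` columns.
#' @return F1 dosage matrix, one row per cross, rownames `female_x_male`.
#' @export
f1_genotypes <- function(panel, plan) {
  missing_ids <- setdiff(unique(c(plan$female, plan$male)), rownames(panel))
  if (length(missing_ids) > 0)
    abort_stage("breeding_workflows", paste0(
      "unknown parent id(s): ", paste(missing_ids, collapse = ", ")))
  het <- any(panel == 1L, na.rm = TRUE)
  if (het)
    warning("f1_genotypes: panel contains heterozygous loci; expected-dosage rule applied")
  F1 <- (panel[plan$female, , drop = FALSE] +
           panel[plan$male, , drop = FALSE]) / 2
  rownames(F1) <- paste0(plan$female, "_x_", plan$male)
  F1
}

#' Rank candidate crosses by predicted F1 phenotype
#'
#' Builds (or takes) the F1 genotypes of each candidate pair, predicts
#' their phenotype with a trained model and ranks the crosses. Ties are
#' broken by (female, male) lexical order, making the ranking
#' deterministic; the top five crosses (all, if fewer than five) are
#' flagged.
#'
#' @param panel inbred dosage matrix (ignored when `f1_geno` is supplied).
#' @param plan data.frame with `female`, `male` columns.
#' @param weights a `gs_weights` object.
#' @param direction `"maximize"` (default) or `"minimize"`.
#' @param f1_geno optional pre-made F1 dosage matrix, one row per plan row
#'   (e.g. read from a VCF of candidate combinations).
#' @param env_ids,env_data passed to [gs_predict()] for environment-aware
#'   models.
#' @return data.frame `female, male, prediction, rank, top5`, ordered by
#'   rank.
#' @export
select_parents <- function(panel, plan, weights,
                           direction = c("maximize", "minimize"),
                           f1_geno = NULL, env_ids = NULL,
                           env_data = NULL) {
  direction <- match.arg(direction)
  if (nrow(plan) == 0)
    abort_stage("breeding_workflows", "empty cross plan")
  F1 <- f1_geno %||% f1_genotypes(panel, plan)
  if (nrow(F1) != nrow(plan))
    abort_stage("breeding_workflows", "f1_geno rows do not match the plan")
  pred <- gs_predict(weights, F1, env_ids = env_ids, env_data = env_data)
  key <- if (direction == "maximize") -pred else pred
  ord <- order(key, plan$female, plan$male)
  out <- data.frame(female = plan$female[ord], male = plan$male[ord],
                    prediction = unname(pred[ord]),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  out$top5 <- out$rank <= 5
  out
}

# ---- file-based workflow runners ---------------------------------------

manifest_write <- function(command, inputs, outputs, seed, config_list,
                           path) {
  mf <- list(
    command = command,
    seed = seed,
    config = config_list,
    inputs = lapply(inputs[file.exists(unlist(inputs))],
                    function(f) list(path = f,
                                     md5 = unname(tools::md5sum(f)))),
    outputs = lapply(outputs[file.exists(unlist(outputs))],
                     function(f) list(path = f,
                                      md5 = unname(tools::md5sum(f)))),
    version = as.character(utils::packageVersion("autogs")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(mf, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

load_filtered_genotypes <- function(vcf, genes = NULL, up = 2000,
                                    down = 1000, filter = TRUE,
                                    strand_aware = TRUE) {
  d <- read_vcf(vcf)
  keep <- if (filter) filter_variants(d$variants) else
    rep(TRUE, nrow(d$variants))
  G <- d$genotypes[, keep, drop = FALSE]
  vt <- d$variants[keep, , drop = FALSE]
  if (!is.null(genes)) {
    gm <- load_genes(genes)
    win <- expand_window(gm, up = up, down = down,
                         strand_aware = strand_aware)
    idx <- select_snps(vt, win)
    if (length(idx) == 0)
      abort_stage("regulatory_selection", "no SNPs fall inside the regulatory windows")
    G <- G[, idx, drop = FALSE]
    vt <- vt[idx, , drop = FALSE]
  }
  list(genotypes = impute_missing(G), variants = vt)
}

#' Train a model from files (workflow runner)
#'
#' Composes the pipeline VCF -> hard filter -> optional regulatory-window
#' selection -> encoding -> training, writes the weights archive and a run
#' manifest (inputs, seed, config, output hashes).
#'
#' @param vcf genotype VCF path.
#' @param pheno phenotype CSV path.
#' @param model model name (see [model_spec()]).
#' @param out_weights weights archive output path.
#' @param genes optional GFF3/BED gene file enabling regulatory-window SNP
#'   selection.
#' @param env_csv weather CSV (required for `EnvSE`).
#' @param seed model seed.
#' @param config a [gs_config()].
#' @param up,down regulatory window extensions (bp).
#' @param hyper hyperparameter overrides for [model_spec()].
#' @return list with `weights`, `r_test`, `weights_path`, `manifest_path`.
#' @export
run_train <- function(vcf, pheno, model, out_weights,
                      genes = NULL, env_csv = NULL, seed = 1L,
                      config = gs_config(), up = 2000, down = 1000,
                      hyper = list()) {
  spec <- model_spec(model, hyper = hyper, seed = seed)  # validate early
  if (model == "EnvSE" && is.null(env_csv))
    abort_stage("breeding_workflows",
                "EnvSE training requires --env (weather CSV)")
  dat <- load_filtered_genotypes(vcf, genes, up, down)
  ph <- read_phenotypes(pheno)
  env_data <- if (!is.null(env_csv)) read_env_csv(env_csv)
  w <- gs_train(dat$genotypes, ph, spec, config, env_data)
  save_weights(w, out_weights)
  h <- w$training$history
  if (!is.null(h)) {
    writeLines(c("epoch	train_mse	val_mse",
                 sprintf("%d	%.6g	%.6g", seq_along(h$train_loss),
                         h$train_loss,
                         c(h$val_loss,
                           rep(NA, length(h$train_loss) -
                                 length(h$val_loss))))),
               paste0(out_weights, ".log"))
  }
  mpath <- paste0(out_weights, ".manifest.json")
  manifest_write("train",
                 c(vcf = vcf, pheno = pheno, genes = genes,
                   env_csv = env_csv),
                 c(weights = out_weights), seed,
                 list(model = model, up = up, down = down), mpath)
  list(weights = w, r_test = w$r_test, weights_path = out_weights,
       manifest_path = mpath)
}

#' Predict phenotypes from files (workflow runner)
#'
#' @param vcf genotype VCF of the prediction population.
#' @param weights_path weights archive from [run_train()].
#' @param out_csv prediction CSV output path.
#' @param env_csv weather CSV for environment-aware models.
#' @param env_id single environment id applied to all samples (or a vector,
#'   one per sample).
#' @return list with `predictions` (data.frame) and output paths.
#' @export
run_predict <- function(vcf, weights_path, out_csv, env_csv = NULL,
                        env_id = NULL) {
  w <- load_weights(weights_path)
  d <- read_vcf(vcf)
  G <- impute_missing(d$genotypes)
  env_data <- if (!is.null(env_csv)) read_env_csv(env_csv)
  env_ids <- if (!is.null(env_id)) rep_len(env_id, nrow(G))
  p <- gs_predict(w, G, env_ids = env_ids, env_data = env_data)
  out <- data.frame(sample = names(p), prediction = unname(p),
                    stringsAsFactors = FALSE)
  if (!is.null(env_ids)) out$env <- env_ids
  write_predictions(out, out_csv)
  mpath <- paste0(out_csv, ".manifest.json")
  manifest_write("predict",
                 c(vcf = vcf, weights = weights_path, env_csv = env_csv),
                 c(predictions = out_csv), w$spec$seed, list(), mpath)
  list(predictions = out, out_csv = out_csv, manifest_path = mpath)
}

#' Integrated training and prediction (workflow runner)
#'
#' Equivalent to [run_train()] followed by [run_predict()] on the same
#' genotypes; given the same seed the outputs are identical.
#'
#' @inheritParams run_train
#' @param predict_vcf VCF of the population to predict (defaults to the
#'   training VCF).
#' @param out_csv prediction CSV output path.
#' @param env_id environment id(s) for prediction (EnvSE).
#' @return list combining the training and prediction results.
#' @export
run_train_predict <- function(vcf, pheno, model, out_weights, out_csv,
                              predict_vcf = NULL, genes = NULL,
                              env_csv = NULL, env_id = NULL, seed = 1L,
                              config = gs_config(), up = 2000,
                              down = 1000, hyper = list()) {
  tr <- run_train(vcf, pheno, model, out_weights, genes = genes,
                  env_csv = env_csv, seed = seed, config = config,
                  up = up, down = down, hyper = hyper)
  pr <- run_predict(predict_vcf %||% vcf, out_weights, out_csv,
                    env_csv = env_csv, env_id = env_id)
  c(tr, pr)
}

#' Select optimal parents from files (workflow runner)
#'
#' Reads an inbred panel VCF plus a plain-text list of line ids, builds the
#' cross plan (all pairs, or the pairs in `pairs_csv`), predicts every F1
#' with the supplied model weights and writes the full ranking plus the
#' top-5 subset.
#'
#' @param panel_vcf VCF of the inbred panel (or of pre-made F1 combinations
#'   when `f1_vcf = TRUE`).
#' @param lines_txt text file: one parent id per line, female ids first;
#'   lines starting `#` ignored. Format: `id,role` with role `female` or
#'   `male`, or bare ids (then `n_female` must be given via `pairs_csv`).
#' @param weights_path weights archive path.
#' @param out_csv full-ranking CSV path; the top-5 subset goes to
#'   `<out_csv>.top5.csv`.
#' @param pairs_csv optional CSV `female,male` restricting the plan.
#' @param direction `"maximize"` or `"minimize"`.
#' @param env_csv,env_id environment inputs for EnvSE weights.
#' @return list with `ranking` data.frame and output paths.
#' @export
run_select_parents <- function(panel_vcf, lines_txt, weights_path, out_csv,
                               pairs_csv = NULL,
                               direction = "maximize", env_csv = NULL,
                               env_id = NULL) {
  w <- load_weights(weights_path)
  d <- read_vcf(panel_vcf)
  panel <- impute_missing(d$genotypes)
  lines <- read_lines_file(lines_txt)
  plan <- if (!is.null(pairs_csv)) {
    pc <- utils::read.csv(pairs_csv, stringsAsFactors = FALSE)
    data.frame(female = as.character(pc[[1]]), male = as.character(pc[[2]]),
               stringsAsFactors = FALSE)
  } else {
    cross_plan(lines$female, lines$male)
  }
  env_data <- if (!is.null(env_csv)) read_env_csv(env_csv)
  env_ids <- if (!is.null(env_id)) rep_len(env_id, nrow(plan))
  ranking <- select_parents(panel, plan, w, direction = direction,
                            env_ids = env_ids, env_data = env_data)
  utils::write.csv(ranking, out_csv, row.names = FALSE, quote = FALSE)
  top_path <- paste0(out_csv, ".top5.csv")
  utils::write.csv(ranking[ranking$top5, , drop = FALSE], top_path,
                   row.names = FALSE, quote = FALSE)
  mpath <- paste0(out_csv, ".manifest.json")
  manifest_write("select-parents",
                 c(panel_vcf = panel_vcf, lines = lines_txt,
                   weights = weights_path, pairs = pairs_csv,
                   env_csv = env_csv),
                 c(ranking = out_csv, top5 = top_path), w$spec$seed,
                 list(direction = direction), mpath)
  list(ranking = ranking, out_csv = out_csv, top5_csv = top_path,
       manifest_path = mpath)
}

read_lines_file <- function(path) {
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  parts <- strsplit(ln, ",")
  if (all(lengths(parts) == 2)) {
    ids <- vapply(parts, `[`, character(1), 1)
    role <- tolower(vapply(parts, `[`, character(1), 2))
    if (!all(role %in% c("female", "male")))
      abort_stage("breeding_workflows", "line roles must be 'female' or 'male'")
    list(female = ids[role == "female"], male = ids[role == "male"])
  } else {
    abort_stage("breeding_workflows",
                "lines file must be 'id,role' with role female/male")
  }
}

#' Integrated training and parent selection (workflow runner)
#'
#' @inheritParams run_train
#' @inheritParams run_select_parents
#' @param out_csv ranking CSV path.
#' @return list combining training and selection results.
#' @export
run_train_select <- function(vcf, pheno, model, out_weights, panel_vcf,
                             lines_txt, out_csv, pairs_csv = NULL,
                             direction = "maximize", genes = NULL,
                             env_csv = NULL, env_id = NULL, seed = 1L,
                             config = gs_config(), hyper = list()) {
  tr <- run_train(vcf, pheno, model, out_weights, genes = genes,
                  env_csv = env_csv, seed = seed, config = config,
                  hyper = hyper)
  sel <- run_select_parents(panel_vcf, lines_txt, out_weights, out_csv,
                            pairs_csv = pairs_csv, direction = direction,
                            env_csv = env_csv, env_id = env_id)
  c(tr, sel)
}
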