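#' Training configuration
#'
#' Defaults follow the standard deep genomic-prediction protocol: Adam with
#' learning rate 1e-3, batch size 64 (clipped to the training-set size),
#' mean-squared-error loss, at most 200 epochs with early stopping on
#' validation MSE (patience 20, best weights restored).
#'
#' @param batch_size mini-batch size.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param lr Adam learning rate.
#' @param weight_decay decoupled L2 penalty applied to the neural models
#'   weight matrices (never biases); regularizes the high-capacity CNNs.
#' @param env_mode aggregation resolution for environment features
#'   (`daily`, `weekly`, `biweekly`).
#' @param env_window number of leading days of the weather series to use
#'   (default: full series).
#' @return a `gs_config` list.
#' @export
gs_config <- function(batch_size = 64, epochs = 200, patience = 20,
                      lr = 1e-3, weight_decay = 0.5,
                      env_mode = "weekly", env_window = NULL) {
  structure(list(batch_size = batch_size, epochs = epochs,
                 patience = patience, lr = lr,
                 weight_decay = weight_decay, env_mode = env_mode,
                 env_window = env_window), class = "gs_config")
}

#' Split samples 8:1:1 into train/validation/test
#'
#' `floor(n/10)` samples go to validation and to test; the remainder trains.
#' The shuffle is a pure function of `seed`.
#'
#' @param n number of samples.
#' @param seed integer seed.
#' @return list with disjoint, exhaustive integer vectors `train`, `val`,
#'   `test`.
#' @export
split_811 <- function(n, seed) {
  stopifnot(n >= 3)
  set.seed(seed)
  perm <- sample.int(n)
  k <- n %/% 10
  if (k == 0) {
    # tiny n: hold out one sample each for val and test
    k <- 1L
  }
  list(test = sort(perm[seq_len(k)]),
       val = sort(perm[k + seq_len(k)]),
       train = sort(perm[(2 * k + 1):n]))
}

#' Pearson correlation between predictions and observations
#'
#' The standard evaluation metric (R) for genomic-prediction models.
#' Requires at least two pairs and non-constant vectors; a constant vector
#' is an error rather than a silent `NA`.
#'
#' @param pred,true numeric vectors of equal length.
#' @return the correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(pred, true) {
  if (length(pred) != length(true))
    abort_stage("training_eval", "pred and true differ in length")
  if (length(pred) < 2)
    abort_stage("training_eval", "need at least 2 observations for R")
  if (stats::sd(pred) < 1e-300 || stats::sd(true) < 1e-300)
    abort_stage("training_eval", "constant vector: R is undefined")
  stats::cor(pred, true)
}

# Build the encoded model input for a set of records. Fit-time artifacts
# (PCA projection, env feature matrix) are created by gs_train from the
# training rows only and reused here.
encode_for_model <- function(spec, G, records = NULL, pca = NULL,
                             env_features = NULL) {
  switch(spec$encoding,
    dosage_vector = {
      X <- encode_dosage(G)$tensor
      if (spec$name == "EnvSE") {
        if (is.null(env_features) || is.null(records$env))
          abort_stage("model_pool", "EnvSE requires environment features")
        unknown <- setdiff(unique(records$env), rownames(env_features))
        if (length(unknown) > 0)
          abort_stage("model_pool", paste0(
            "unknown environment id(s): ", paste(unknown, collapse = ", ")))
        list(geno = X, env = env_features[records$env, , drop = FALSE])
      } else X
    },
    onehot_4xL = encode_onehot_4xL(G)$tensor,
    soy_3xSxS = suppressWarnings(encode_soy(G)$tensor),
    pca_150 = apply_pca(G, pca)$tensor,
    abort_stage("model_pool", paste0("unknown encoding ", spec$encoding)))
}

slice_records <- function(X, idx) slice_input(X, idx)

#' Train a genomic-prediction model
#'
#' Runs the full training protocol: matches phenotype records to genotype
#' rows, splits 8:1:1 by the spec's seed, fits encoding artifacts (PCA
#' projection, environment-feature standardization) on the training rows
#' only, trains the model with Adam/MSE and early stopping, and evaluates
#' Pearson R on the held-out test split.
#'
#' @param genotypes samples x loci dosage matrix (imputed automatically if
#'   missing entries remain).
#' @param phenotypes data.frame from [read_phenotypes()]; an `env` column
#'   is required for `EnvSE`.
#' @param spec a [model_spec()].
#' @param config a [gs_config()].
#' @param env_data weather table ([read_env_csv()] or simulator output);
#'   required for `EnvSE`.
#' @return a `gs_weights` object with the fitted model, every encoding
#'   artifact needed at prediction time, training history and `r_test`.
#' @export
gs_train <- function(genotypes, phenotypes, spec, config = gs_config(),
                     env_data = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (anyNA(genotypes)) genotypes <- impute_missing(genotypes)
  ids <- rownames(genotypes)
  if (is.null(ids)) abort_stage("training_eval", "genotype matrix lacks sample ids")
  records <- phenotypes[phenotypes$sample %in% ids, , drop = FALSE]
  dropped <- nrow(phenotypes) - nrow(records)
  if (dropped > 0)
    message(sprintf("gs_train: %d phenotype record(s) without genotypes dropped", dropped))
  if (nrow(records) < 10)
    abort_stage("training_eval", "need at least 10 matched samples to train")
  G <- genotypes[records$sample, , drop = FALSE]
  n <- nrow(records)
  split <- split_811(n, spec$seed)

  pca <- NULL
  if (spec$encoding == "pca_150")
    pca <- fit_pca(G[split$train, , drop = FALSE],
                   k = hp(spec, "pca_k", 150))
  env_features <- NULL
  if (spec$name == "EnvSE") {
    if (is.null(env_data))
      abort_stage("model_pool", "EnvSE requires env_data (weather CSV)")
    if (is.null(records$env))
      abort_stage("model_pool", "EnvSE requires an 'env' phenotype column")
    env_features <- env_feature_matrix(env_data, config$env_mode,
                                       config$env_window)
  }
  X <- encode_for_model(spec, G, records, pca, env_features)
  y <- records$value

  model <- build_model(spec)
  model$fit(slice_records(X, split$train), y[split$train],
            slice_records(X, split$val), y[split$val], config)
  pred_test <- model$predict(slice_records(X, split$test))
  r_test <- tryCatch(pearson_r(pred_test, y[split$test]),
                     error = function(e) {
                       warning(conditionMessage(e))
                       NA_real_
                     })
  history <- if (!is.null(model$history)) model$history else
    if (exists("history", envir = model)) model$history else NULL
  structure(list(
    spec = spec,
    model_state = model$state(),
    encoding = list(kind = spec$encoding,
                    locus_map = colnames(genotypes),
                    pca = pca,
                    env_mode = config$env_mode,
                    env_window = config$env_window,
                    env_features = env_features),
    training = list(seed = spec$seed, n = n, split_sizes = lengths(split),
                    history = history),
    r_test = r_test,
    version = as.character(utils::packageVersion("autogs"))),
    class = "gs_weights")
}

#' @export
print.gs_weights <- function(x, ...) {
  cat(sprintf("gs_weights: %s (%s encoding), %d loci, test R = %s\n",
              x$spec$name, x$encoding$kind, length(x$encoding$locus_map),
              formatC(x$r_test, digits = 3, format = "f")))
  invisible(x)
}

#' Predict phenotypes from fitted model weights
#'
#' @param weights a `gs_weights` object from [gs_train()] or
#'   [load_weights()].
#' @param genotypes dosage matrix over the same loci the model was trained
#'   on (checked against the stored locus map).
#' @param env_ids character vector of environment ids, one per genotype
#'   row; required for `EnvSE`.
#' @param env_data weather table; defaults to the training-time feature
#'   matrix stored in the weights.
#' @param config optional [gs_config()] (environment aggregation settings
#'   when `env_data` is supplied).
#' @return numeric vector of predictions, named by sample.
#' @export
gs_predict <- function(weights, genotypes, env_ids = NULL, env_data = NULL,
                       config = NULL) {
  stopifnot(inherits(weights, "gs_weights"))
  if (anyNA(genotypes)) genotypes <- impute_missing(genotypes)
  map <- weights$encoding$locus_map
  if (!is.null(map)) {
    got <- colnames(genotypes)
    if (length(got) != length(map) || !all(got == map)) {
      if (all(map %in% got)) {
        # superset VCF: subset to the training loci by key
        genotypes <- genotypes[, map, drop = FALSE]
      } else {
        abort_stage("training_eval", sprintf(
          "locus mismatch: weights were trained on %d loci, supplied %d (keys differ)",
          length(map), length(got)))
      }
    }
  }
  env_features <- weights$encoding$env_features
  if (!is.null(env_data))
    env_features <- env_feature_matrix(
      env_data,
      (config %||% gs_config())$env_mode %||% weights$encoding$env_mode,
      weights$encoding$env_window)
  records <- if (weights$spec$name == "EnvSE") {
    if (is.null(env_ids))
      abort_stage("model_pool", "EnvSE prediction requires env_ids")
    data.frame(sample = rownames(genotypes), env = env_ids,
               stringsAsFactors = FALSE)
  } else NULL
  X <- encode_for_model(weights$spec, genotypes, records,
                        weights$encoding$pca, env_features)
  model <- build_model(weights$spec)
  model$restore(weights$model_state)
  p <- model$predict(X)
  names(p) <- rownames(genotypes)
  p
}

#' Save model weights to a single-archive file
#'
#' The archive is text: a magic line, a JSON metadata header, a base64
#' payload (the serialized `gs_weights` object) and an MD5 checksum of the
#' payload. Round trips are bit-exact, so saved models predict identically
#' after reload.
#'
#' @param weights a `gs_weights` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_weights <- function(weights, path) {
  stopifnot(inherits(weights, "gs_weights"))
  payload <- jsonlite::base64_enc(serialize(weights, NULL, version = 2))
  payload <- gsub("\n", "", payload, fixed = TRUE)
  meta <- jsonlite::toJSON(list(
    model = weights$spec$name, encoding = weights$encoding$kind,
    n_loci = length(weights$encoding$locus_map),
    seed = weights$spec$seed, r_test = weights$r_test,
    version = weights$version), auto_unbox = TRUE, digits = NA)
  writeLines(c("AUTOGSW1", as.character(meta), payload,
               md5_string(payload)), path)
  invisible(path)
}

md5_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}

#' Load model weights saved by [save_weights()]
#'
#' Verifies the magic line and the payload checksum before deserializing.
#'
#' @param path archive path.
#' @return the `gs_weights` object.
#' @export
load_weights <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4 || lines[1] != "AUTOGSW1")
    abort_stage("training_eval", "not an autogs weights file (bad magic)")
  payload <- lines[3]
  if (md5_string(payload) != lines[4])
    abort_stage("training_eval", "weights file corrupted (checksum mismatch)")
  w <- unserialize(jsonlite::base64_dec(payload))
  if (!inherits(w, "gs_weights"))
    abort_stage("training_eval", "weights payload is not a gs_weights object")
  w
}
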