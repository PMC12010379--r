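#' @title Environmental feature vectors
#' @description Daily weather series are summarised into per-environment
#'   feature vectors from 11 variables: maximum/minimum temperature,
#'   humidity, precipitation, wind speed, sea-level pressure, cloud cover,
#'   solar radiation, solar energy, UV index and sunlight duration. The
#'   series can enter the model at daily, weekly or biweekly resolution;
#'   coarser modes average over 7- or 14-day bins (a partial trailing bin is
#'   averaged over its available days).
#' @name env_features
NULL

#' The 11 environmental variable names, in canonical column order
#' @export
env_var_names <- c("tempmax", "tempmin", "humidity", "precip", "windspeed",
                   "sealevelpressure", "cloudcover", "solarradiation",
                   "solarenergy", "uvindex", "sunhours")

#' Read an environment weather CSV
#'
#' Expects columns `env,date` followed by the 11 variables of
#' [env_var_names] (any order, matched by name).
#'
#' @param path CSV path.
#' @return data.frame ordered by (env, date).
#' @export
read_env_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("env", "date", env_var_names)
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols) > 0)
    abort_stage("model_pool", paste0("environment CSV lacks column(s): ",
                                     paste(missing_cols, collapse = ", ")))
  df <- df[order(df$env, df$date), need]
  if (any(!vapply(df[env_var_names], is.numeric, logical(1))))
    abort_stage("model_pool", "non-numeric environmental variable values")
  df
}

#' Aggregate one environment's daily series into a feature vector
#'
#' @param series data.frame of one environment's consecutive days with the
#'   [env_var_names] columns (extra columns ignored).
#' @param mode `daily` keeps all days, `weekly`/`biweekly` average over
#'   7-/14-day bins; a partial trailing bin is averaged over its days.
#' @param window_days number of leading days to use (default: all).
#' @return named numeric vector of length `11 * n_bins`, variable-major.
#' @export
aggregate_env <- function(series, mode = c("daily", "weekly", "biweekly"),
                          window_days = NULL) {
  mode <- match.arg(mode)
  nd <- if (is.null(window_days)) nrow(series) else
    min(window_days, nrow(series))
  M <- as.matrix(series[seq_len(nd), env_var_names, drop = FALSE])
  bin <- switch(mode, daily = 1L, weekly = 7L, biweekly = 14L)
  groups <- (seq_len(nd) - 1L) %/% bin + 1L
  agg <- rowsum(M, groups) / as.vector(table(groups))
  out <- as.vector(agg)                       # variable-major (bins fastest)
  names(out) <- as.vector(outer(seq_len(nrow(agg)), env_var_names,
                                function(b, v) paste0(v, "_b", b)))
  out
}

#' Build the environments x features matrix from a weather table
#'
#' @param env_df data.frame from [read_env_csv()] (or the simulator).
#' @param mode,window_days passed to [aggregate_env()].
#' @return numeric matrix with one row per environment id (rownames set).
#' @export
env_feature_matrix <- function(env_df, mode = "weekly",
                               window_days = NULL) {
  envs <- sort(unique(env_df$env))
  rows <- lapply(envs, function(e)
    aggregate_env(env_df[env_df$env == e, , drop = FALSE], mode,
                  window_days))
  len <- vapply(rows, length, integer(1))
  if (length(unique(len)) != 1)
    abort_stage("model_pool",
                "environments have different series lengths; supply window_days")
  m <- do.call(rbind, rows)
  rownames(m) <- envs
  m
}
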