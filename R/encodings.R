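#' @title Genotype encodings for the model pool
#' @description Each model family consumes a different view of the imputed
#'   dosage matrix: classical ML models and DeepGS use the raw L-dimensional
#'   dosage vector; DLGWAS uses a (4, L) one-hot matrix (hom-ref, het,
#'   hom-alt, missing); SoyDNGP one-hot encodes 3 genotype classes and
#'   reshapes the first S^2 loci (S = floor(sqrt(L))) into a (3, S, S)
#'   tensor; DNNGP projects onto the top 150 principal components fitted on
#'   the training samples only. Every encoder is deterministic.
#' @name encodings
NULL

encoded_input <- function(kind, tensor, layout, locus_map) {
  structure(list(kind = kind, tensor = tensor, layout = layout,
                 locus_map = locus_map), class = "encoded_input")
}

check_imputed <- function(G) {
  if (anyNA(G)) abort_stage("encodings", "genotype matrix has missing entries; run impute_missing() first")
}

#' Encode genotypes as allele-dosage vectors
#'
#' @param G imputed samples x loci dosage matrix.
#' @return `encoded_input` of kind `dosage_vector`; tensor is the numeric
#'   (n, L) matrix.
#' @export
encode_dosage <- function(G) {
  check_imputed(G)
  X <- matrix(as.numeric(G), nrow(G), ncol(G), dimnames = dimnames(G))
  encoded_input("dosage_vector", X, c(n = nrow(G), L = ncol(G)),
                colnames(G) %||% seq_len(ncol(G)))
}

#' Encode genotypes as a (4, L) one-hot matrix per sample
#'
#' Channel order is fixed: hom-ref (dosage 0), het (1), hom-alt (2),
#' missing. Missing entries are permitted here (channel 4); exactly one
#' channel is hot per (sample, locus).
#'
#' @param G samples x loci dosage matrix, `NA` allowed.
#' @return `encoded_input` of kind `onehot_4xL`; tensor has dim (n, 4, L).
#' @export
encode_onehot_4xL <- function(G) {
  n <- nrow(G); L <- ncol(G)
  tensor <- array(0, dim = c(n, 4, L))
  tensor[, 1, ][G == 0L & !is.na(G)] <- 1
  tensor[, 2, ][G == 1L & !is.na(G)] <- 1
  tensor[, 3, ][G == 2L & !is.na(G)] <- 1
  tensor[, 4, ][is.na(G)] <- 1
  encoded_input("onehot_4xL", tensor, c(n = n, channels = 4, L = L),
                colnames(G) %||% seq_len(L))
}

#' Encode genotypes as a (3, S, S) square one-hot tensor per sample
#'
#' The first `S^2` loci (`S = floor(sqrt(L))`) are one-hot encoded over the
#' three genotype classes (hom-ref, het, hom-alt) and laid out row-major
#' into an S x S image; the trailing `L - S^2` loci are dropped with a
#' warning.
#'
#' @param G imputed samples x loci dosage matrix, `L >= 4`.
#' @return `encoded_input` of kind `soy_3xSxS`; tensor has dim (n, 3, S, S);
#'   `locus_map` holds the indices of the loci used.
#' @export
encode_soy <- function(G) {
  check_imputed(G)
  L <- ncol(G)
  if (L < 4) abort_stage("encodings", "soy encoding needs at least 4 loci")
  S <- floor(sqrt(L))
  used <- seq_len(S * S)
  if (L > S * S)
    warning(sprintf("encode_soy: dropping %d trailing locus/loci (L=%d, S=%d)",
                    L - S * S, L, S))
  n <- nrow(G)
  Gs <- G[, used, drop = FALSE]
  tensor <- array(0, dim = c(n, 3, S, S))
  # row-major layout: locus (i-1)*S + j -> pixel (row i, col j)
  for (cls in 0:2) {
    M <- (Gs == cls) * 1
    dim(M) <- c(n, S, S)            # locus index = j + (k-1)*S -> (col j fills fastest)
    tensor[, cls + 1, , ] <- aperm(M, c(1, 3, 2))
  }
  encoded_input("soy_3xSxS", tensor, c(n = n, channels = 3, S = S, S = S),
                (colnames(G) %||% seq_len(L))[used])
}

#' Fit a PCA projection on training genotypes
#'
#' Centers by per-locus training means and keeps the top `k` components
#' (default 150). Fitting on training samples only — and storing the
#' projection inside the model weights — prevents test-set leakage. Sign
#' convention: the largest-magnitude loading of each component is positive,
#' making the projection deterministic.
#'
#' @param G_train imputed training dosage matrix.
#' @param k number of components; reduced to `min(n_train - 1, L)` with a
#'   warning when the data cannot support `k`.
#' @return a `pca_projection` with fields `rotation` (L x k), `center`,
#'   `explained` (variance fractions) and `locus_map`.
#' @export
fit_pca <- function(G_train, k = 150) {
  check_imputed(G_train)
  n <- nrow(G_train); L <- ncol(G_train)
  kmax <- min(n - 1L, L)
  if (k > kmax) {
    warning(sprintf("fit_pca: k reduced from %d to %d (n_train=%d, L=%d)",
                    k, kmax, n, L))
    k <- kmax
  }
  pc <- stats::prcomp(G_train, center = TRUE, scale. = FALSE, rank. = k)
  rot <- pc$rotation
  flip <- apply(rot, 2, function(v) v[which.max(abs(v))] < 0)
  rot[, flip] <- -rot[, flip]
  structure(list(rotation = rot, center = pc$center,
                 explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
                 locus_map = colnames(G_train) %||% seq_len(L)),
            class = "pca_projection")
}

#' Project genotypes onto a fitted PCA basis
#'
#' @param G imputed dosage matrix over the same loci the projection was
#'   fitted on (checked via `locus_map`).
#' @param proj a [fit_pca()] result.
#' @return `encoded_input` of kind `pca_150`; tensor is the (n, k) score
#'   matrix.
#' @export
apply_pca <- function(G, proj) {
  check_imputed(G)
  stopifnot(inherits(proj, "pca_projection"))
  map <- colnames(G) %||% seq_len(ncol(G))
  if (length(map) != length(proj$locus_map) || !all(map == proj$locus_map))
    abort_stage("encodings", "locus_map mismatch: PCA was fitted on a different locus set")
  scores <- sweep(G, 2, proj$center) %*% proj$rotation
  encoded_input("pca_150", scores, c(n = nrow(G), k = ncol(scores)),
                proj$locus_map)
}
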