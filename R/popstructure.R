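# Population structure: allele frequencies, PCA with Patterson scaling,
# and discriminant analysis of principal components (DAPC).

#' Per-population alternate-allele frequencies
#'
#' Frequency of the counted (dosage) allele per population per SNP,
#' computed as allele count / (2 x non-missing individuals). Cells where
#' every genotype is missing are `NA` (undefined).
#'
#' @param G dosage matrix (individuals x SNPs).
#' @param labels population (or group) label per individual.
#' @return numeric matrix SNPs x populations.
#' @export
allele_frequencies <- function(G, labels) {
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(G))
  pops <- unique(labels)
  if (nrow(G) == 0L || length(pops) == 0L) stop("empty population")
  out <- matrix(NA_real_, ncol(G), length(pops),
                dimnames = list(colnames(G), pops))
  for (p in pops) {
    sub <- G[labels == p, , drop = FALSE]
    if (nrow(sub) == 0L) stop("empty population: ", p)
    nonmiss <- colSums(!is.na(sub))
    f <- colSums(sub, na.rm = TRUE) / (2 * nonmiss)
    f[nonmiss == 0L] <- NA_real_
    out[, p] <- f
  }
  out
}

#' Principal component analysis of SNP genotypes
#'
#' Missing dosages are mean-imputed per SNP, columns are centered at
#' `2 * p_hat` and, under Patterson scaling, divided by
#' `sqrt(2 * p_hat * (1 - p_hat))` (the binomial sd of one genotype under
#' Hardy-Weinberg); the scaled matrix is then decomposed by SVD. SNPs
#' monomorphic after imputation carry no information and are dropped with
#' a warning. Component signs are fixed so each loading vector's
#' largest-magnitude entry is positive.
#'
#' @param G dosage matrix (individuals x SNPs), >= 2 individuals.
#' @param scaling `"patterson"` (default) or `"center"` (no variance
#'   scaling).
#' @return an object of class `snp_pca`: list with `coordinates`
#'   (individuals x components), `eigenvalues` (variances along
#'   components, non-increasing), `pct_variance` (summing to 100),
#'   `loadings`, and `kept` (indices of SNPs used).
#' @export
snp_pca <- function(G, scaling = c("patterson", "center")) {
  scaling <- match.arg(scaling)
  if (nrow(G) < 2L) stop("PCA needs at least 2 individuals")
  X <- apply(G, 2L, function(col) {
    m <- mean(col, na.rm = TRUE)
    col[is.na(col)] <- m
    col
  })
  p <- colMeans(X) / 2
  keep <- which(p > 0 & p < 1 & apply(X, 2L, function(v) any(v != v[1L])))
  if (length(keep) < ncol(X))
    warning(ncol(X) - length(keep),
            " zero-variance SNP(s) dropped before PCA")
  if (length(keep) == 0L) stop("no polymorphic SNPs for PCA")
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  X <- sweep(X, 2L, 2 * p)
  if (scaling == "patterson")
    X <- sweep(X, 2L, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(X)
  n <- nrow(X)
  # sign convention: largest-|loading| entry positive per component
  for (k in seq_along(sv$d)) {
    j <- which.max(abs(sv$v[, k]))
    if (sv$v[j, k] < 0) {
      sv$v[, k] <- -sv$v[, k]
      sv$u[, k] <- -sv$u[, k]
    }
  }
  ev <- sv$d^2 / (n - 1)
  res <- list(coordinates = sv$u %*% diag(sv$d, length(sv$d)),
              eigenvalues = ev,
              pct_variance = 100 * ev / sum(ev),
              loadings = sv$v,
              kept = keep,
              scaling = scaling)
  rownames(res$coordinates) <- rownames(G)
  class(res) <- "snp_pca"
  res
}

#' @export
print.snp_pca <- function(x, ...) {
  cat("SNP PCA (", x$scaling, " scaling): ", nrow(x$coordinates),
      " individuals, ", length(x$kept), " SNPs\n", sep = "")
  k <- min(5L, length(x$pct_variance))
  cat("  % variance:", paste0(sprintf("PC%d=%.2f", seq_len(k),
                                      x$pct_variance[seq_len(k)]),
                              collapse = " "), "\n")
  invisible(x)
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Step 1 reduces the genotypes to `n_pcs` principal components; step 2
#' performs linear discriminant analysis on the PC scores, finding axes
#' that maximize the between-group to within-group variance ratio
#' (generalized eigenproblem `B a = lambda W a`, solved via a Cholesky
#' whitening of `W`). This reveals genetic differences between groups
#' while minimizing the variation within them.
#'
#' @param G dosage matrix.
#' @param groups group label per individual (>= 2 groups).
#' @param n_pcs number of PCs retained; default: smallest number
#'   explaining >= 80% of total variance.
#' @param n_axes number of discriminant axes (default
#'   `min(n_groups - 1, n_pcs)`).
#' @param scaling passed to [snp_pca()].
#' @return an object of class `snp_dapc`: list with `retained_pc_count`,
#'   `coordinates` (individuals x axes), `centroids` (groups x axes),
#'   `discrimination_ratio` (per-axis between/within variance ratio,
#'   non-increasing), `axes` (directions in PC-score space) and `pca`.
#' @export
snp_dapc <- function(G, groups, n_pcs = NULL, n_axes = NULL,
                     scaling = "patterson") {
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(G))
  glev <- unique(groups)
  if (length(glev) < 2L) stop("DAPC needs at least 2 groups")
  pca <- snp_pca(G, scaling = scaling)
  if (is.null(n_pcs)) {
    n_pcs <- which(cumsum(pca$pct_variance) >= 80)[1L]
    if (is.na(n_pcs)) n_pcs <- length(pca$pct_variance)
  }
  n_pcs <- min(n_pcs, sum(pca$eigenvalues > 1e-9))
  S <- pca$coordinates[, seq_len(n_pcs), drop = FALSE]
  n <- nrow(S)
  gm <- colMeans(S)
  W <- matrix(0, n_pcs, n_pcs)
  B <- matrix(0, n_pcs, n_pcs)
  for (g in glev) {
    Sg <- S[groups == g, , drop = FALSE]
    mg <- colMeans(Sg)
    cg <- sweep(Sg, 2L, mg)
    W <- W + crossprod(cg)
    B <- B + nrow(Sg) * tcrossprod(mg - gm)
  }
  W <- W / (n - length(glev))
  B <- B / (length(glev) - 1L)
  R <- tryCatch(chol(W), error = function(e)
    stop("singular within-group scatter (a group may have too few members ",
         "for n_pcs = ", n_pcs, ")"))
  Ri <- backsolve(R, diag(n_pcs))
  M <- crossprod(Ri, B %*% Ri)        # symmetric whitened between-scatter
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  n_axes_max <- min(length(glev) - 1L, n_pcs)
  if (is.null(n_axes)) n_axes <- n_axes_max
  n_axes <- min(n_axes, n_axes_max)
  A <- Ri %*% eig$vectors[, seq_len(n_axes), drop = FALSE]
  for (k in seq_len(n_axes)) {          # same sign convention as PCA
    j <- which.max(abs(A[, k]))
    if (A[j, k] < 0) A[, k] <- -A[, k]
  }
  coords <- S %*% A
  centroids <- t(vapply(glev, function(g)
    colMeans(coords[groups == g, , drop = FALSE]), numeric(n_axes)))
  if (n_axes == 1L) centroids <- matrix(centroids, ncol = 1L,
                                        dimnames = list(glev, NULL))
  res <- list(retained_pc_count = n_pcs,
              coordinates = coords,
              centroids = centroids,
              discrimination_ratio = eig$values[seq_len(n_axes)],
              axes = A,
              groups = groups,
              pca = pca)
  rownames(res$coordinates) <- rownames(G)
  class(res) <- "snp_dapc"
  res
}

#' @export
print.snp_dapc <- function(x, ...) {
  cat("DAPC: ", length(unique(x$groups)), " groups, ",
      x$retained_pc_count, " PCs retained, ",
      ncol(x$coordinates), " discriminant axis/axes\n", sep = "")
  cat("  between/within ratio:",
      paste(sprintf("%.3g", x$discrimination_ratio), collapse = " "), "\n")
  invisible(x)
}

#' Write PCA/DAPC coordinates as TSV
#' @param x a `snp_pca` or `snp_dapc` object.
#' @param path output path.
#' @param n_components how many leading components to write (default 10).
#' @return `path`, invisibly.
#' @export
write_coordinates <- function(x, path, n_components = 10L) {
  co <- x$coordinates
  k <- min(n_components, ncol(co))
  df <- data.frame(sample_id = rownames(co) %||% seq_len(nrow(co)),
                   co[, seq_len(k), drop = FALSE])
  names(df)[-1L] <- paste0("axis", seq_len(k))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
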