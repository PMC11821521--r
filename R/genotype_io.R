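# PLINK binary genotype input/output, dosage standardization and covariate
# residualization. Dosages count copies of allele1 (the A1 column of the bim
# file): bed code 00 -> 2, 10 -> 1, 11 -> 0, 01 -> missing.

.BED_MAGIC <- as.raw(c(0x6C, 0x1B))
.BED_SNP_MAJOR <- as.raw(0x01)

# 256 x 4 lookup: byte value + 1 -> dosages of the 4 samples packed in it
.bed_decode_lut <- local({
  code_map <- c(2L, NA_integer_, 1L, 0L) # two-bit codes 00, 01, 10, 11
  lut <- matrix(NA_integer_, 256L, 4L)
  for (b in 0:255) {
    v <- b
    for (k in 1:4) {
      lut[b + 1L, k] <- code_map[(v %% 4L) + 1L]
      v <- v %/% 4L
    }
  }
  lut
})

#' Construct a genotype matrix object
#'
#' Bundles a dosage matrix with sample and variant metadata. Dosages are
#' integer counts of allele1 in `{0, 1, 2}` with `NA` for missing calls.
#'
#' @param dosages integer matrix, samples x variants.
#' @param samples data.frame with at least columns `fid`, `iid`.
#' @param variants data.frame with columns `chrom`, `id`, `pos`, `a1`, `a2`.
#' @return An object of class `genotype_matrix` with fields `dosages`,
#'   `samples`, `variants` (including a recomputed `maf` column) and
#'   `chromosome_index`, a named list mapping each chromosome to its column
#'   indices.
#' @export
genotype_matrix <- function(dosages, samples, variants) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  stopifnot(nrow(samples) == nrow(dosages), nrow(variants) == ncol(dosages))
  bad <- !(dosages %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  f <- colMeans(dosages, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA_real_
  variants$maf <- pmin(f, 1 - f)
  if (any(variants$pos <= 0, na.rm = TRUE)) stop("variant positions must be positive")
  chroms <- as.character(variants$chrom)
  idx <- split(seq_len(ncol(dosages)), factor(chroms, levels = unique(chroms)))
  structure(
    list(dosages = dosages, samples = as.data.frame(samples),
         variants = as.data.frame(variants), chromosome_index = idx),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages), length(x$chromosome_index)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Read PLINK bed/bim/fam genotypes
#'
#' Decodes a SNP-major PLINK 1 binary fileset (magic bytes `6C 1B`, mode
#' `01`, two bits per genotype with per-variant byte padding).
#'
#' @param bed_path,bim_path,fam_path file paths; `bim_path` and `fam_path`
#'   default to the bed path with the extension swapped.
#' @return A [genotype_matrix()].
#' @export
read_bed <- function(bed_path,
                     bim_path = sub("\\.bed$", ".bim", bed_path),
                     fam_path = sub("\\.bed$", ".fam", bed_path)) {
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  bim <- if (file.size(bim_path) == 0) {
    data.frame(chrom = character(0), id = character(0), cm = numeric(0),
               pos = integer(0), a1 = character(0), a2 = character(0))
  } else {
    data.table::fread(bim_path, header = FALSE,
                      col.names = c("chrom", "id", "cm", "pos", "a1", "a2"),
                      colClasses = list(character = c(1, 2, 5, 6)),
                      data.table = FALSE)
  }
  fam <- data.table::fread(fam_path, header = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
                           colClasses = list(character = c(1, 2)),
                           data.table = FALSE)
  if (anyDuplicated(bim$id)) warning("duplicate variant IDs in bim; retained")
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bed_path, what = "raw", n = file.size(bed_path))
  if (length(raw) < 3L || !identical(raw[1:2], .BED_MAGIC)) {
    stop("not a PLINK bed file (bad magic bytes)")
  }
  if (!identical(raw[3L], .BED_SNP_MAJOR)) {
    stop("unsupported bed mode byte (only SNP-major 0x01 is supported)")
  }
  bpv <- ceiling(n / 4)
  if (length(raw) - 3L != bpv * m) {
    stop(sprintf("bed payload has %d bytes; expected %d for %d samples x %d variants",
                 length(raw) - 3L, bpv * m, n, m))
  }
  if (m == 0L || n == 0L) {
    dos <- matrix(integer(0), n, m)
  } else {
    dec <- .bed_decode_lut[as.integer(raw[-(1:3)]) + 1L, , drop = FALSE]
    dos <- matrix(t(dec), nrow = 4L * bpv, ncol = m)[seq_len(n), , drop = FALSE]
  }
  genotype_matrix(dos, fam[, c("fid", "iid")],
                  bim[, c("chrom", "id", "pos", "a1", "a2")])
}

#' Write PLINK bed/bim/fam genotypes
#'
#' Inverse of [read_bed()]: `read_bed(write_bed(G, prefix))` reproduces `G`
#' exactly, and the bed payload is byte-identical on re-encode (padding bits
#' are zero).
#'
#' @param G a [genotype_matrix()].
#' @param prefix output path prefix; writes `prefix.bed/.bim/.fam`.
#' @return the prefix, invisibly.
#' @export
write_bed <- function(G, prefix) {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- nrow(G$dosages); m <- ncol(G$dosages)
  bpv <- ceiling(n / 4)
  # dosage -> two-bit code (NA -> 01)
  codes <- matrix(0L, 4L * bpv, max(m, 1L))
  if (m > 0L) {
    cmap <- c(3L, 2L, 0L) # dosage 0,1,2 -> code 11,10,00
    d <- G$dosages
    cc <- matrix(1L, nrow(d), ncol(d)) # missing -> 01
    ok <- !is.na(d)
    cc[ok] <- cmap[d[ok] + 1L]
    codes <- rbind(cc, matrix(0L, 4L * bpv - n, m))
    dim(codes) <- c(4L, bpv * m)
    bytes <- as.raw(colSums(codes * c(1L, 4L, 16L, 64L)))
  } else {
    bytes <- raw(0)
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(c(.BED_MAGIC, .BED_SNP_MAJOR, bytes), con)
  v <- G$variants
  data.table::fwrite(data.frame(v$chrom, v$id, rep(0L, nrow(v)), v$pos, v$a1, v$a2),
                     paste0(prefix, ".bim"), sep = "\t", col.names = FALSE)
  s <- G$samples
  fam <- data.frame(fid = s$fid, iid = s$iid, pat = 0L, mat = 0L, sex = 0L, pheno = -9L)
  data.table::fwrite(fam, paste0(prefix, ".fam"), sep = "\t", col.names = FALSE)
  invisible(prefix)
}

#' Standardize genotype dosages
#'
#' Mean-imputes missing calls, centers each variant and divides by a scale:
#' the observed (population) standard deviation for `mode = "empirical"` or
#' `sqrt(2 f (1 - f))` with `f` the counted-allele frequency for
#' `mode = "binomial"`. Zero-variance (monomorphic or all-missing) columns
#' are flagged and excluded. Optionally projects covariates out of every
#' column afterwards, so the result is a covariate-adjusted genotype matrix
#' ready for model fitting.
#'
#' @param G a [genotype_matrix()].
#' @param mode scale convention, `"empirical"` (default) or `"binomial"`.
#' @param covariates optional numeric matrix or data.frame of covariates
#'   (an intercept is always added) to residualize out of each column.
#' @return An object of class `adjusted_matrix`: `values` (N x M_kept),
#'   `center`, `scale`, `keep` (logical over the original columns),
#'   `variants` (metadata for kept columns), `chromosome_index` (remapped to
#'   kept columns) and `adjustment_basis` (the covariate matrix with
#'   intercept, or NULL).
#' @export
standardize <- function(G, mode = c("empirical", "binomial"), covariates = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  mode <- match.arg(mode)
  d <- G$dosages
  if (length(d) == 0L) stop("empty genotype matrix")
  X <- matrix(as.double(d), nrow(d), ncol(d))
  mu <- colMeans(X, na.rm = TRUE)
  all_missing <- is.nan(mu)
  if (any(all_missing)) {
    warning(sum(all_missing), " all-missing variant(s) excluded")
    mu[all_missing] <- 0
  }
  na_idx <- which(is.na(X))
  if (length(na_idx)) {
    X[na_idx] <- mu[((na_idx - 1L) %/% nrow(X)) + 1L]
  }
  X <- sweep(X, 2L, mu, "-")
  pop_sd <- sqrt(colMeans(X^2))
  scale_col <- switch(mode,
    empirical = pop_sd,
    binomial = {
      f <- mu / 2
      sqrt(2 * f * (1 - f))
    }
  )
  keep <- pop_sd > 0 & scale_col > 0 & !all_missing
  if (!any(keep)) stop("no polymorphic variants after standardization")
  if (any(!keep & !all_missing)) {
    message(sum(!keep & !all_missing), " zero-variance variant(s) excluded")
  }
  X <- sweep(X[, keep, drop = FALSE], 2L, scale_col[keep], "/")
  basis <- NULL
  if (!is.null(covariates)) {
    C <- .covariate_basis(covariates, nrow(X))
    X <- .project_out(X, C)
    basis <- C
  }
  old2new <- cumsum(keep)
  idx <- lapply(G$chromosome_index, function(ix) unname(old2new[ix[keep[ix]]]))
  idx <- idx[vapply(idx, length, 1L) > 0L]
  structure(
    list(values = X, center = mu[keep], scale = scale_col[keep], keep = keep,
         variants = G$variants[keep, , drop = FALSE],
         chromosome_index = idx, adjustment_basis = basis),
    class = "adjusted_matrix"
  )
}

.covariate_basis <- function(C, n) {
  if (is.null(C)) return(matrix(1, n, 1, dimnames = list(NULL, "intercept")))
  C <- as.matrix(C)
  storage.mode(C) <- "double"
  stopifnot(nrow(C) == n)
  cbind(intercept = 1, C)
}

.project_out <- function(Y, C) {
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    bad <- colnames(C)[qrC$pivot[seq(qrC$rank + 1L, ncol(C))]]
    if (is.null(bad)) bad <- qrC$pivot[seq(qrC$rank + 1L, ncol(C))]
    stop("covariate matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  Y - qr.fitted(qrC, Y)
}

#' Regress covariates out of a phenotype (or any) matrix
#'
#' Returns `Y - C (C'C)^-1 C' Y` after appending an intercept to `C`; output
#' columns are orthogonal to the span of the covariates. Idempotent.
#'
#' @param Y numeric vector or N x T matrix.
#' @param C covariate matrix (or NULL for intercept-only centering).
#' @return matrix of residuals with the same shape as `Y`.
#' @export
residualize_covariates <- function(Y, C = NULL) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  .project_out(Y, .covariate_basis(C, nrow(Y)))
}

#' Read a whitespace-delimited phenotype or covariate table
#'
#' Expects a header row whose first two columns are FID and IID; missing
#' values coded NA. All remaining columns are returned as numeric.
#'
#' @param path file path.
#' @return data.frame with columns `fid`, `iid` and one numeric column per
#'   trait/covariate.
#' @export
read_pheno_table <- function(path) {
  d <- data.table::fread(path, header = TRUE, na.strings = c("NA", "-9"),
                         colClasses = list(character = 1:2), data.table = FALSE)
  if (ncol(d) < 3L) stop("expected FID IID plus at least one value column in ", path)
  names(d)[1:2] <- c("fid", "iid")
  for (j in seq(3L, ncol(d))) d[[j]] <- as.numeric(d[[j]])
  d
}

#' Align a phenotype/covariate table to genotype samples
#'
#' Joins on (FID, IID); genotype samples absent from the table are dropped
#' with a logged count.
#'
#' @param G a [genotype_matrix()].
#' @param tab data.frame from [read_pheno_table()].
#' @return list with the subset `genotype_matrix` and the reordered table.
#' @export
align_samples <- function(G, tab) {
  key_g <- paste(G$samples$fid, G$samples$iid, sep = "\r")
  key_t <- paste(tab$fid, tab$iid, sep = "\r")
  pos <- match(key_g, key_t)
  ok <- !is.na(pos)
  if (!all(ok)) message(sum(!ok), " genotyped sample(s) missing from table; dropped")
  Gs <- genotype_matrix(G$dosages[ok, , drop = FALSE],
                        G$samples[ok, , drop = FALSE], G$variants)
  list(genotypes = Gs, table = tab[pos[ok], , drop = FALSE])
}
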