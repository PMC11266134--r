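#' Read a genotype matrix from delimited text or a minimal VCF
#'
#' Delimited files must carry a header row of marker ids and a first column of
#' sample ids; cells are genotype codes in the declared coding. Cells equal to
#' `missing_token` (or unparseable) become `NA`. Files ending in `.vcf` are
#' read through the vcfR package: diploid unphased GT fields are decoded to
#' 0/1/2 dosages (multi-allelic records are rejected) and samples become rows.
#'
#' @param path file path.
#' @param coding `"MINUS1_0_1"` (default) or `"ZERO_1_2"`; VCF input is always
#'   dosage-coded and is read as `"ZERO_1_2"`.
#' @param missingToken string marking a missing genotype (default "NA").
#' @return a [GenotypeMatrix-class].
#' @export
loadGenotypes <- function(path, coding = c("MINUS1_0_1", "ZERO_1_2"),
                          missingToken = "NA") {
  coding <- match.arg(coding)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
    return(.loadGenotypesVcf(path))
  dt <- data.table::fread(path, header = TRUE, na.strings = missingToken,
                          colClasses = list(character = 1L), data.table = FALSE)
  if (ncol(dt) < 2L) stop("no marker columns found in '", path, "'")
  ids <- dt[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate sample ids in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(dt[, -1L, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop("duplicate marker ids in '", path, "'")
  suppressWarnings(storage.mode(m) <- "integer")
  rownames(m) <- ids
  codes <- if (coding == "ZERO_1_2") c(0L, 1L, 2L) else c(-1L, 0L, 1L)
  bad <- !is.na(m) & !(m %in% codes)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("genotype entry outside the %s coding set at row '%s', column '%s'",
                 coding, rownames(m)[idx[1L]], colnames(m)[idx[2L]]))
  }
  genotypeMatrix(m, coding = coding)
}

.loadGenotypesVcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF input requires the vcfR package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(vcf)
  if (any(grepl(",", alt)))
    stop("multi-allelic VCF records are not supported")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ids <- vcfR::getID(vcf)
  if (any(is.na(ids)) || anyDuplicated(ids))
    ids <- paste0(vcfR::getCHROM(vcf), ":", vcfR::getPOS(vcf))
  dose <- function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1L]]
    if (length(al) != 2L || any(!al %in% c("0", "1"))) return(NA_integer_)
    sum(al == "1")
  }
  m <- apply(gt, c(1, 2), dose)           # markers x samples
  m <- t(m)                               # samples x markers
  colnames(m) <- ids
  genotypeMatrix(m, coding = "ZERO_1_2")
}

#' Read a phenotype table into a list of TraitVectors
#'
#' First column holds sample ids; every remaining column is a numeric trait.
#' Non-numeric cells become missing values and survive until [dropMissing].
#'
#' @param path delimited text file.
#' @return named list of [TraitVector-class], in column order.
#' @export
loadPhenotypes <- function(path) {
  dt <- data.table::fread(path, header = TRUE, colClasses = list(character = 1L),
                          data.table = FALSE)
  if (ncol(dt) < 2L) stop("no trait columns found in '", path, "'")
  ids <- dt[[1L]]
  if (anyDuplicated(ids)) stop("duplicate sample ids in '", path, "'")
  traits <- lapply(names(dt)[-1L], function(nm) {
    v <- suppressWarnings(as.numeric(dt[[nm]]))
    traitVector(stats::setNames(v, ids), traitName = nm)
  })
  names(traits) <- names(dt)[-1L]
  numericish <- vapply(traits, function(t) any(is.finite(traitValues(t))),
                       logical(1))
  if (!any(numericish)) stop("no numeric trait columns in '", path, "'")
  traits
}

#' Write genotypes / one phenotype back to TSV
#'
#' Inverse of the loaders: `writeGenotypes(loadGenotypes(f))` reproduces cell
#' values exactly (in the canonical -1/0/1 coding).
#'
#' @param G a GenotypeMatrix.
#' @param t a TraitVector.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeGenotypes <- function(G, path) {
  df <- data.frame(id = sampleIds(G), genotypes(G), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGenotypes
#' @export
writePhenotype <- function(t, path) {
  df <- data.frame(id = sampleIds(t), value = traitValues(t),
                   check.names = FALSE)
  names(df)[2L] <- t@traitName
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove samples and markers with missing data
#'
#' Aligns `G` and `t` on their shared sample ids, then removes, in order:
#' samples with a missing phenotype, samples with any missing genotype, and
#' finally markers with any missing genotype among the remaining samples.
#' The order is fixed (configurable via `order`) because the removal criterion
#' alone does not determine the result.
#'
#' @param G a GenotypeMatrix.
#' @param t a TraitVector sharing sample ids with `G`.
#' @param order `"samples_first"` (default, as above) or `"markers_first"`
#'   (markers with missing genotypes dropped before genotype-missing samples).
#' @param verbose emit a removal log via `message()`.
#' @return list with elements `genotypes`, `trait`, and `removed` (a summary
#'   of what was dropped).
#' @export
dropMissing <- function(G, t, order = c("samples_first", "markers_first"),
                        verbose = FALSE) {
  order <- match.arg(order)
  shared <- intersect(sampleIds(G), sampleIds(t))
  if (!length(shared)) stop("no shared sample ids between genotypes and trait")
  G <- G[shared, ]
  t <- t[shared]
  y <- traitValues(t)
  keepPheno <- !is.na(y)
  G <- G[keepPheno, ]; t <- t[keepPheno]
  v <- genotypes(G)
  if (order == "samples_first") {
    keepS <- rowSums(is.na(v)) == 0L
    v <- v[keepS, , drop = FALSE]
    keepM <- colSums(is.na(v)) == 0L
    v <- v[, keepM, drop = FALSE]
    t <- t[keepS]
  } else {
    keepM <- colSums(is.na(v)) == 0L
    v <- v[, keepM, drop = FALSE]
    keepS <- rowSums(is.na(v)) == 0L
    v <- v[keepS, , drop = FALSE]
    t <- t[keepS]
  }
  if (nrow(v) == 0L) stop("all samples removed by missing-data filtering")
  if (ncol(v) == 0L) stop("all markers removed by missing-data filtering")
  removed <- list(samplesMissingPheno = sum(!keepPheno),
                  samplesMissingGeno = sum(!keepS),
                  markersMissingGeno = sum(!keepM))
  if (verbose)
    message(sprintf(paste0("dropMissing: removed %d sample(s) with missing ",
                           "phenotype, %d with missing genotype, %d marker(s)"),
                    removed$samplesMissingPheno, removed$samplesMissingGeno,
                    removed$markersMissingGeno))
  list(genotypes = genotypeMatrix(v), trait = t, removed = removed)
}

#' Standardize a trait using training-split statistics
#'
#' Subtracts the training mean and divides by the training standard deviation;
#' the same affine transform is applied to every entry, so test values are on
#' the training scale without leakage. `unstandardizeTrait` inverts it.
#'
#' @param t a TraitVector.
#' @param trainIndex indices (or sample ids) of the training subset.
#' @return a standardized TraitVector with `center`/`scale` recorded.
#' @export
standardizeTrait <- function(t, trainIndex = seq_along(traitValues(t))) {
  y <- traitValues(t)
  ytr <- y[trainIndex]
  if (!length(ytr)) stop("empty training index")
  ctr <- mean(ytr, na.rm = TRUE)
  scl <- stats::sd(ytr, na.rm = TRUE)
  if (!is.finite(scl) || scl < 1e-12)
    stop("zero training variance: trait '", t@traitName, "' cannot be standardized")
  traitVector((y - ctr) / scl, traitName = t@traitName, standardized = TRUE,
              center = ctr, scale = scl)
}

#' @rdname standardizeTrait
#' @export
unstandardizeTrait <- function(t) {
  if (!t@standardized) return(t)
  traitVector(traitValues(t) * t@scale + t@center, traitName = t@traitName,
              standardized = FALSE)
}

#' Genotype-class frequencies over all entries
#'
#' The averaged ratio of the three genotype codes over all samples and markers
#' - the quantity that distinguishes two-homozygote, homozygote+heterozygote
#' and three-class marker panels.
#'
#' @param G a GenotypeMatrix with no missing entries.
#' @return named numeric vector `c(freq_aa, freq_Aa, freq_AA)` summing to 1.
#' @export
genotypeRatios <- function(G) {
  v <- genotypes(G)
  if (length(v) == 0L) stop("empty genotype matrix")
  if (anyNA(v)) stop("genotypeRatios requires a matrix without missing entries")
  n <- length(v)
  c(freq_aa = sum(v == -1L) / n,
    freq_Aa = sum(v == 0L) / n,
    freq_AA = sum(v == 1L) / n)
}
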