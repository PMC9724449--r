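## TSV I/O for catalogues, signature sets and activity matrices.
## External layout follows the COSMIC/PCAWG distribution files: tab-separated,
## header row, UTF-8; catalogues and signatures with a "MutationType" label
## column and one column per sample/signature. Both orientations are accepted
## on read (the 96 labels identify the channel axis).

.readTSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    sep = "\t")
}

## internal: TSV with a label column -> numeric matrix with channel labels on
## one dimension, handed to .orientToSamplesByChannels for reordering
.readChannelMatrix <- function(path) {
  df <- .readTSV(path)
  if (ncol(df) < 2L) stop("expected a label column plus data columns: ", path)
  labs <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric data column(s) in ", path)
  rownames(m) <- labs
  .orientToSamplesByChannels(m)
}

#' Read a mutation catalogue from TSV
#'
#' Accepts the COSMIC/PCAWG layout (rows = the 96 channels, first column the
#' channel label — any of \code{MutationType}, \code{Type}, ... — one column
#' per sample) or its transpose. Channels are reordered to the canonical
#' scheme; counts must be non-negative integers.
#'
#' @param path Path to a tab-separated file.
#' @param cancerType Optional per-sample labels, or a 2-column TSV path
#'   (sample, type).
#' @return A \linkS4class{MutationCatalog}.
#' @seealso \code{\link{writeCatalog}}, \code{\link{readSignatures}}
#' @export
readCatalog <- function(path, cancerType = character()) {
  m <- .readChannelMatrix(path)
  if (any(m < 0)) stop("negative count(s) in ", path)
  if (any(abs(m - round(m)) > 1e-9)) stop("non-integer count(s) in ", path)
  if (length(cancerType) == 1L && file.exists(cancerType)) {
    tab <- .readTSV(cancerType)
    cancerType <- tab[[2L]][match(rownames(m), tab[[1L]])]
  }
  MutationCatalog(round(m), cancerType = cancerType)
}

#' Read a signature set from TSV
#'
#' Same layout as catalogues, with signature names in place of sample names.
#' Rows within 1e-6 of unit sum are renormalised; larger deviations or
#' negative entries are an error.
#'
#' @param path Path to a tab-separated file.
#' @return A \linkS4class{SignatureSet}.
#' @export
readSignatures <- function(path) {
  SignatureSet(.readChannelMatrix(path))
}

#' Read an activity matrix from TSV
#'
#' Samples as rows (first column sample id), signatures as columns.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix, samples x signatures, all entries non-negative.
#' @export
readActivities <- function(path) {
  df <- .readTSV(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  if (!is.numeric(m) || any(!is.finite(m))) {
    stop("activities must be finite numeric: ", path)
  }
  if (any(m < 0)) stop("negative activit(ies) in ", path)
  m
}

#' Write a mutation catalogue as TSV
#'
#' Written channels x samples with a leading \code{MutationType} column (the
#' COSMIC layout), so \code{writeCatalog} then \code{\link{readCatalog}}
#' round-trips exactly.
#'
#' @param catalog A \linkS4class{MutationCatalog}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeCatalog <- function(catalog, path) {
  stopifnot(is(catalog, "MutationCatalog"))
  .writeChannelMatrix(mutationCounts(catalog), path)
}

#' Write a signature set as TSV
#'
#' @param signatures A \linkS4class{SignatureSet}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeSignatures <- function(signatures, path) {
  stopifnot(is(signatures, "SignatureSet"))
  .writeChannelMatrix(signatureProfiles(signatures), path)
}

.writeChannelMatrix <- function(m, path) {
  df <- data.frame(MutationType = colnames(m), t(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an activity matrix as TSV
#'
#' @param activities Numeric matrix, samples x signatures.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeActivities <- function(activities, path) {
  df <- data.frame(Sample = rownames(activities), activities,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize / read back a modulatory fit
#'
#' Two TSVs: \code{<stem>_profile.tsv} (channel, r) and
#' \code{<stem>_activities.tsv} (sample, c).
#'
#' @param fit A \linkS4class{ModulatoryFit}.
#' @param stem Output path stem.
#' @return Invisibly, the two paths written.
#' @export
writeModulatoryFit <- function(fit, stem) {
  stopifnot(is(fit, "ModulatoryFit"))
  p1 <- paste0(stem, "_profile.tsv")
  p2 <- paste0(stem, "_activities.tsv")
  utils::write.table(
    data.frame(Channel = names(modProfile(fit)), r = modProfile(fit)),
    p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(Sample = names(modActivities(fit)), c = modActivities(fit)),
    p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}

#' @rdname writeModulatoryFit
#' @export
readModulatoryFit <- function(stem) {
  pr <- .readTSV(paste0(stem, "_profile.tsv"))
  ac <- .readTSV(paste0(stem, "_activities.tsv"))
  ModulatoryFit(r = structure(pr$r, names = pr$Channel),
                c = structure(ac$c, names = ac$Sample))
}

#' Add a pseudo-count to a catalogue
#'
#' Used where divisions or log transforms would otherwise hit zero (the
#' multiplicative residual); never applied to the Poisson likelihood, where
#' zero counts are valid observations.
#'
#' @param catalog A \linkS4class{MutationCatalog}.
#' @param value Positive pseudo-count, default 1.
#' @return A new \linkS4class{MutationCatalog}; the input is untouched.
#' @export
#' @examples
#' m <- matrix(rpois(96 * 2, 5), nrow = 2,
#'             dimnames = list(c("a", "b"), sbsChannels()))
#' ct <- MutationCatalog(m)
#' all(mutationCounts(applyPseudocount(ct)) == mutationCounts(ct) + 1)
applyPseudocount <- function(catalog, value = 1) {
  stopifnot(is(catalog, "MutationCatalog"), value > 0)
  new("MutationCatalog", counts = mutationCounts(catalog) + value,
      cancerType = cancerType(catalog))
}
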