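#' The six SBS base substitution classes
#'
#' Single-base substitutions are reported relative to the pyrimidine of the
#' mutated base pair, giving six base classes.
#'
#' @return Character vector of the six substitution classes, in canonical
#'   order: \code{C>A, C>G, C>T, T>A, T>C, T>G}.
#' @export
#' @examples
#' sbsBaseClasses()
sbsBaseClasses <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

#' Canonical 96-channel SBS mutation-type labels
#'
#' The 96 trinucleotide-context channels: each of the six pyrimidine-centred
#' base substitutions in its 16 possible 5'/3' single-base contexts, labelled
#' COSMIC-style, e.g. \code{"A[C>A]A"}. Ordering is by base class, then
#' alphabetically by 5' flank, then 3' flank — the COSMIC convention.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(sbsChannels())
sbsChannels <- function() {
  bases <- c("A", "C", "G", "T")
  unlist(lapply(sbsBaseClasses(), function(cls) {
    as.vector(t(outer(bases, bases, function(f, t3) {
      paste0(f, "[", cls, "]", t3)
    })))
  }), use.names = FALSE)
}

#' Base substitution class of each channel
#'
#' @param channels Character vector of channel labels such as
#'   \code{"A[C>A]A"}; defaults to the canonical 96.
#' @return Character vector of the same length giving the base class
#'   (e.g. \code{"C>A"}) of each channel.
#' @export
#' @examples
#' table(channelBaseClass())
channelBaseClass <- function(channels = sbsChannels()) {
  m <- regmatches(channels, regexpr("[CT]>[ACGT]", channels))
  if (length(m) != length(channels)) {
    stop("malformed channel label(s): ",
         paste(channels[!grepl("[CT]>[ACGT]", channels)], collapse = ", "))
  }
  if (!all(m %in% sbsBaseClasses())) {
    stop("unknown base class in channel label(s)")
  }
  m
}

## internal: validate a set of labels against the canonical scheme and return
## the permutation mapping them onto canonical order
.channelPermutation <- function(labels) {
  canon <- sbsChannels()
  if (anyDuplicated(labels)) {
    stop("duplicate channel label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  extra <- setdiff(labels, canon)
  if (length(extra)) {
    stop("unknown channel label(s): ", paste(extra, collapse = ", "))
  }
  missing <- setdiff(canon, labels)
  if (length(missing)) {
    stop("missing channel(s): ", paste(missing, collapse = ", "))
  }
  match(canon, labels)
}
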