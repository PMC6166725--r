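# Sliding-window hydrophobicity profiling and proline-aromatic motif
# scanning of substrate sequences.

#' Built-in hydrophobicity scales
#'
#' Per-residue hydrophobicity values, positive = hydrophobic. The default
#' scale is Roseman's (1988) side-chain hydrophobicity scale (pi-r,
#' kcal/mol), the scale conventionally used for chaperone substrate
#' profiling of unfolded chains. Alternative scales can be supplied to
#' [hydrophobicity_profile()] as a named numeric vector over the 20
#' standard one-letter codes.
#'
#' @param name scale name; currently `"roseman"`.
#' @return named numeric vector of length 20.
#' @export
#' @examples
#' hydrophobicity_scale()[c("W", "D")]
hydrophobicity_scale <- function(name = "roseman") {
  scales <- list(
    roseman = c(
      A =  0.39, R = -3.95, N = -1.91, D = -3.81, C =  0.25,
      Q = -1.30, E = -2.91, G =  0.00, H = -0.64, I =  1.82,
      L =  1.82, K = -2.77, M =  0.96, F =  2.27, P =  0.99,
      S = -1.24, T = -1.00, W =  2.13, Y =  1.47, V =  1.30)
  )
  if (!name %in% names(scales))
    stop(sprintf("unknown hydrophobicity scale '%s'", name))
  scales[[name]]
}

split_sequence <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1L]]
  toupper(sequence)
}

#' Windowed hydrophobicity profile of a protein sequence
#'
#' Computes the mean per-residue hydrophobicity over a centred sliding
#' window. Terminal positions where the full window does not fit are
#' reported as `NA` (undefined), never zero-filled or computed from a
#' shrunken window, so that chain termini carry no silently biased scores.
#'
#' @param sequence amino-acid string (or character vector of one-letter
#'   codes).
#' @param window odd window width in residues; the conventional choice for
#'   unfolded-chain profiling is 9.
#' @param scale a scale name understood by [hydrophobicity_scale()] or a
#'   named numeric vector of per-residue values.
#' @param on_unknown what to do with non-standard residue letters:
#'   `"error"` (default) or `"na"` (treat as undefined; windows containing
#'   them are undefined as well).
#' @return an object of class `sequence_profile`: a data frame with columns
#'   `position`, `aa`, `score` (window mean, `NA` where undefined) plus
#'   attributes `window` and `sequence`.
#' @export
#' @examples
#' p <- hydrophobicity_profile("ADKWWLVAEKDDA", window = 5)
#' hydrophobic_stretches(p)
hydrophobicity_profile <- function(sequence, window = 9, scale = "roseman",
                                   on_unknown = c("error", "na")) {
  on_unknown <- match.arg(on_unknown)
  aa <- split_sequence(sequence)
  n <- length(aa)
  if (n < 1L) stop("empty sequence")
  if (window < 1 || window %% 2 != 1)
    stop("'window' must be an odd integer >= 1")
  if (window > n)
    stop("'window' is wider than the sequence")
  vals <- if (is.character(scale)) hydrophobicity_scale(scale) else scale
  per <- unname(vals[aa])
  unknown <- !(aa %in% names(vals))
  if (any(unknown)) {
    if (on_unknown == "error")
      stop(sprintf("unknown residue letter(s): %s",
                   paste(unique(aa[unknown]), collapse = ", ")))
    per[unknown] <- NA_real_
  }
  half <- (window - 1L) / 2L
  score <- rep(NA_real_, n)
  if (n >= window) {
    # centred rolling mean; NA propagates so windows touching an unknown
    # residue stay undefined
    cs <- cumsum(c(0, per))
    idx <- (half + 1L):(n - half)
    score[idx] <- (cs[idx + half + 1L] - cs[idx - half]) / window
  }
  out <- data.frame(position = seq_len(n), aa = aa, score = score,
                    stringsAsFactors = FALSE)
  attr(out, "window") <- window
  attr(out, "sequence") <- paste(aa, collapse = "")
  class(out) <- c("sequence_profile", "data.frame")
  out
}

#' Maximal hydrophobic stretches of a profile
#'
#' Returns the maximal runs of consecutive defined positions whose windowed
#' score exceeds `threshold`. A score above 0 denotes increased
#' hydrophobicity on the default scale, so `threshold = 0` delimits the
#' hydrophobic stretches of the chain.
#'
#' @param profile a [hydrophobicity_profile()] result.
#' @param threshold scores strictly above this value count as hydrophobic.
#' @return data frame with columns `start`, `end` (1-based, inclusive
#'   residue positions), possibly zero rows.
#' @export
hydrophobic_stretches <- function(profile, threshold = 0) {
  hot <- !is.na(profile$score) & profile$score > threshold
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = profile$position[starts[keep]],
             end = profile$position[ends[keep]])
}

#' Scan a sequence for proline-aromatic motifs
#'
#' A proline immediately adjacent to an aromatic residue, sitting inside a
#' hydrophobic stretch, is the recognition element targeted by the
#' chaperone PPIase domain. Every proline with an aromatic neighbour on
#' either side is reported; a proline flanked by aromatics on both sides
#' yields two hits.
#'
#' @param sequence amino-acid string.
#' @param stretches optional data frame of hydrophobic stretches as
#'   returned by [hydrophobic_stretches()]; used to set
#'   `in_hydrophobic_stretch`. When `NULL`, all hits are flagged `NA`.
#' @param aromatics the aromatic alphabet; defaults to W, F, Y, H.
#' @return data frame with columns `proline_position`, `aromatic_position`,
#'   `aromatic_residue`, `in_hydrophobic_stretch`.
#' @export
#' @examples
#' scan_proline_aromatic("AVPWLVA",
#'   stretches = data.frame(start = 1, end = 7))
scan_proline_aromatic <- function(sequence, stretches = NULL,
                                  aromatics = c("W", "F", "Y", "H")) {
  aa <- split_sequence(sequence)
  n <- length(aa)
  hits <- list()
  in_stretch <- function(pos) {
    if (is.null(stretches)) return(NA)
    nrow(stretches) > 0 && any(pos >= stretches$start & pos <= stretches$end)
  }
  for (i in which(aa == "P")) {
    for (j in c(i - 1L, i + 1L)) {
      if (j >= 1L && j <= n && aa[j] %in% aromatics) {
        hits[[length(hits) + 1L]] <- data.frame(
          proline_position = i,
          aromatic_position = j,
          aromatic_residue = aa[j],
          in_hydrophobic_stretch = in_stretch(i),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(proline_position = integer(), aromatic_position = integer(),
                      aromatic_residue = character(),
                      in_hydrophobic_stretch = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of amino-acid strings.
#' @export
read_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  out <- toupper(vapply(seqs, function(s) as.character(s)[1L], character(1L)))
  names(out) <- vapply(seqs, function(s) attr(s, "name"), character(1L))
  out
}
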