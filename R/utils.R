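# Internal helpers shared across modules.

#' Round half away from zero to a fixed number of decimals
#'
#' Base R's `round()` rounds half to even; printed tables in the genomics
#' literature almost universally round half up, so derived statistics meant to
#' be compared against printed values go through this helper.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(0.5)      # 1
#' round_half_up(33.85, 1) # 33.9
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# canonical 1-based position on a circle of length L
canon_pos <- function(p, L) ((p - 1L) %% L) + 1L

# reverse complement of a plain character DNA string (keeps N)
revcomp_chr <- function(s) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

complement_chr <- function(s) chartr("ACGTNacgtn", "TGCANtgcan", s)

# split a string into a character vector of single residues
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# split an in-frame coding string into codons
codon_split <- function(s) {
  n <- nchar(s)
  stopifnot(n %% 3 == 0)
  if (n == 0) return(character(0))
  substring(s, seq(1, n, by = 3), seq(3, n, by = 3))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
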