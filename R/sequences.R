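# Sequence construction and composition metrics for sticker-spacer polymers.

# The four low-complexity domains studied throughout the package, stored as the
# concatenation of their printed 5-residue blocks.
.lcd_sequences <- list(
  "A1-LCD" = paste0(
    "GSMASASSSQRGRSGSGNFGGGRGGGFGGN",
    "DNFGRGGNFSGRGGFGGSRGGGGYGGSGDG",
    "YNGFGNDGSNFGGGGSYNDFGNYNNQSSNF",
    "GPMKGGNFGGRSSGGSGGGGQYFAKPRNQG",
    "GYGGSSSSSSYGSGRRF"),
  "EWSR1-LCD" = paste0(
    "MASTDYSTYSQAAAQQGYSAYTAQPTQGYA",
    "QTTQAYGQQSYGTYGQPTDVSYTQAQTTAT",
    "YGQTAYATSYGQPPTGYTTPTAPQAYSQPV",
    "QGYGTGAYDTTTATVTTTQASYAAQSAYGT",
    "QPAYPAYGQQPAATAPTRPQDGNKPTETSQ",
    "PQSSTGGYNQPSLGYGQSNYSYPQVPGSYP",
    "MQPVTAPPSYPPTSYSSTQPTSYDQSSYSQ",
    "QNTYGQPSSYGQQSSYGQQSSYGQQPPTSY",
    "PPQTGSYSQAPSQYSQQSSSYGQQSSFRQD",
    "HPSSMGVYGQ"),
  "TIA1-LCD" = paste0(
    "MINPVQQQNQIGYPQPYGQWGQWYGNAQQI",
    "GQYMPNGWQVPAYGMYGQAWNQQGFNQTQS",
    "SAPWMGPNYGVQPPQGQNGSMLPNQPSGYR",
    "VAGYETN"),
  "FUS-LCD" = paste0(
    "MASNDYTQQATQSYGAYPTQPGQGYSQQSS",
    "QPYGQQSYSGYSQSTDTSGYGQSSYSSYGQ",
    "SQNTGYGTQSTPQGYGSTGGYGSSQSSQSS",
    "YGQQSSYPGYGQQPAPSSTSGSYGSSSQSS",
    "SYGQPQSGSYSQQPSYGGQQQSYGQQQSYN",
    "PPQGYGQQNQYNS")
)

# Scrambled S120Y30 variant, printed as fixed (not re-randomized) text.
.ys_scrambled <- paste0(
  "SSSSS", "SSSSS", "SSYSS", "YSYYY", "YSSSS", "SSSSS",
  "YSSSS", "SSSSY", "SSSSY", "SSSSS", "SSSYS", "SSSSS",
  "SSSSS", "SYSSY", "YYSSS", "SSSYS", "YSYSS", "SSSSS",
  "YSSSY", "SSYSS", "SSSSS", "YSSSY", "YSSSS", "SYYSY",
  "SYSYS", "SSSSS", "SSSYS", "SSSSS", "SSSSS", "YSSSS")

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a residue sequence object
#'
#' A `residue_seq` is the basic typed container for a bead-resolution polymer:
#' a name plus an ordered string over the 20-letter amino-acid alphabet.
#'
#' @param residues Character scalar of one-letter residue codes (whitespace is
#'   stripped, letters upper-cased).
#' @param name Label for the sequence.
#' @return An object of class `residue_seq` with fields `name`, `residues`
#'   (character scalar) and `n` (residue count).
#' @examples
#' residue_seq("YSYSYS", "demo")
#' @export
residue_seq <- function(residues, name = "seq") {
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (nchar(residues) < 1L) stop("sequence must contain at least one residue")
  chars <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(chars), .aa_alphabet)
  if (length(bad) > 0L) {
    stop("invalid residue code(s): ", paste(bad, collapse = ", "))
  }
  structure(list(name = name, residues = residues, n = nchar(residues)),
            class = "residue_seq")
}

#' @export
print.residue_seq <- function(x, ...) {
  cat(sprintf("<residue_seq> %s (n = %d)\n", x$name, x$n))
  show <- if (x$n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(" ", show, "\n")
  invisible(x)
}

#' @export
as.character.residue_seq <- function(x, ...) x$residues

#' Low-complexity domain sequences
#'
#' Returns one of the four packaged phase-separating LCD sequences:
#' the low-complexity domains of hnRNPA1 ("A1-LCD", n = 137), FUS
#' ("FUS-LCD", n = 163), EWSR1 ("EWSR1-LCD", n = 280) and TIA1
#' ("TIA1-LCD", n = 97).
#'
#' @param name One of `"A1-LCD"`, `"FUS-LCD"`, `"EWSR1-LCD"`, `"TIA1-LCD"`.
#' @return A [residue_seq].
#' @examples
#' build_lcd("TIA1-LCD")$n  # 97
#' @export
build_lcd <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% names(.lcd_sequences)) {
    stop("unknown LCD name; available: ", paste(names(.lcd_sequences), collapse = ", "))
  }
  residue_seq(.lcd_sequences[[name]], name = name)
}

#' Names of the packaged YS sequence variants
#'
#' The ten binary tyrosine/serine variants (all n = 150) spanning an
#' order-of-magnitude range of hydrophobic fraction and blockiness, plus the
#' fixed scrambled variant `"scrambled"` (also written `(S120Y30)scr`).
#'
#' @return Character vector of names accepted by [build_ys_variant()].
#' @export
ys_variant_names <- function() {
  c("(S9Y)15", "(S4Y)30", "(SSY)50", "(YS)75", "(YYS)50", "Y150",
    "(S12Y3)10", "(S24Y6)5", "S120Y30", "scrambled")
}

# Parse a pattern token like "(S4Y)30", "S120Y30", "Y150" into a residue string.
.expand_ys_pattern <- function(pattern) {
  pattern <- gsub("[[:space:]]|x", "", pattern)
  m <- regmatches(pattern, regexec("^\\(([YS0-9]+)\\)([0-9]+)$", pattern))[[1]]
  if (length(m) == 3L) {
    unit <- .expand_ys_pattern(m[2])
    return(strrep(unit, as.integer(m[3])))
  }
  if (!grepl("^([YS][0-9]*)+$", pattern)) {
    stop("cannot parse YS pattern: ", pattern)
  }
  toks <- regmatches(pattern, gregexpr("[YS][0-9]*", pattern))[[1]]
  paste(vapply(toks, function(tk) {
    letter <- substr(tk, 1, 1)
    rep_n <- if (nchar(tk) > 1) as.integer(substr(tk, 2, nchar(tk))) else 1L
    strrep(letter, rep_n)
  }, character(1)), collapse = "")
}

#' Binary YS sequence variants
#'
#' Builds a tyrosine/serine sticker-spacer sequence from a repeat-unit pattern
#' such as `"(S4Y)30"` (the unit `SSSSY` tiled 30 times, left to right),
#' `"S120Y30"` (diblock) or `"Y150"` (homopolymer). `"scrambled"` returns the
#' packaged fixed scrambled counterpart of `S120Y30` — it is a stored string,
#' not a re-randomization. The packaged study variants all have n = 150.
#'
#' @param pattern Pattern string or `"scrambled"`.
#' @param length Expected total length; an error is raised when the expanded
#'   pattern disagrees. Default 150 (the packaged variants); use `NA` to skip
#'   the check.
#' @return A [residue_seq] over the \{Y, S\} alphabet.
#' @examples
#' build_ys_variant("(SSY)50")
#' @export
build_ys_variant <- function(pattern, length = 150L) {
  if (identical(pattern, "scrambled") || identical(pattern, "(S120Y30)scr")) {
    seq <- .ys_scrambled
    name <- "(S120Y30)scr"
  } else {
    seq <- .expand_ys_pattern(pattern)
    name <- pattern
  }
  if (!is.na(length) && nchar(seq) != length) {
    stop(sprintf("pattern '%s' expands to %d residues, expected %d",
                 pattern, nchar(seq), length))
  }
  residue_seq(seq, name = name)
}

#' Hydrophobic (sticker) fraction of a sequence
#'
#' Fraction of residues belonging to the sticker set. For LCDs the default
#' sticker set is the aromatic residues \{F, W, Y\}; for binary YS sequences
#' the set \{Y\} is the natural choice (and gives the same value, as YS
#' sequences contain no F or W).
#'
#' @param seq A [residue_seq].
#' @param sticker_set Character vector of residue codes counted as stickers.
#' @return Fraction in \[0, 1\].
#' @examples
#' hydrophobic_fraction(build_ys_variant("(SSY)50"))  # 1/3
#' @export
hydrophobic_fraction <- function(seq, sticker_set = c("Y", "W", "F")) {
  stopifnot(inherits(seq, "residue_seq"))
  if (length(sticker_set) == 0L) stop("sticker_set must be non-empty")
  chars <- strsplit(seq$residues, "")[[1]]
  mean(chars %in% toupper(sticker_set))
}

#' Sequence blockiness of a binary YS sequence
#'
#' Blockiness quantifies how segregated the stickers are along the chain:
#' `f_B = 1 - B_act / B_max`, where `B_act` counts the actual Y-S and S-Y
#' junctions (adjacent unlike pairs) and `B_max = min(2 * min(nY, nS), n - 1)`
#' is the maximum junction count attainable at that composition. The
#' convention reproduces the defining limits: a strictly alternating sequence
#' gives `f_B = 0` and a diblock gives `f_B -> 1`.
#'
#' @param seq A [residue_seq] over \{Y, S\} only.
#' @return A list of class `sequence_metrics` with `f_h` (fraction of Y),
#'   `f_B`, `B_act`, `B_max` and a `degenerate` flag, set when the sequence is
#'   a homopolymer (`B_max = 0`; `f_B` is then defined as 1).
#' @examples
#' blockiness(build_ys_variant("S120Y30"))$f_B  # 1 - 1/60
#' @export
blockiness <- function(seq) {
  stopifnot(inherits(seq, "residue_seq"))
  chars <- strsplit(seq$residues, "")[[1]]
  if (!all(chars %in% c("Y", "S"))) {
    stop("blockiness is defined for two-letter {Y,S} sequences only")
  }
  n <- length(chars)
  n_y <- sum(chars == "Y")
  n_s <- n - n_y
  b_act <- if (n > 1) sum(chars[-1] != chars[-n]) else 0L
  b_max <- min(2L * min(n_y, n_s), n - 1L)
  degenerate <- b_max == 0L
  f_b <- if (degenerate) 1 else 1 - b_act / b_max
  structure(list(f_h = n_y / n, f_B = f_b, B_act = b_act, B_max = b_max,
                 degenerate = degenerate),
            class = "sequence_metrics")
}

#' @export
print.sequence_metrics <- function(x, ...) {
  cat(sprintf("f_h = %.3f  f_B = %.3f  (B_act = %d, B_max = %d%s)\n",
              x$f_h, x$f_B, x$B_act, x$B_max,
              if (x$degenerate) ", degenerate composition" else ""))
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return Named list of [residue_seq] objects.
#' @export
read_sequences_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  out <- lapply(seq_along(recs), function(i) {
    residue_seq(as.character(recs[[i]]), name = names(recs)[i])
  })
  names(out) <- names(recs)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs A [residue_seq] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequences_fasta <- function(seqs, path) {
  if (inherits(seqs, "residue_seq")) seqs <- list(seqs)
  seqinr::write.fasta(lapply(seqs, function(s) s$residues),
                      names = vapply(seqs, function(s) s$name, character(1)),
                      file.out = path)
  invisible(path)
}

#' Summary table of the packaged study sequences
#'
#' Lengths, sticker fractions and (for YS sequences) blockiness of the four
#' LCDs and the eleven packaged YS variants.
#'
#' @param sticker_set Sticker set used for the LCD hydrophobic fraction.
#' @return A data.frame with columns `name`, `n`, `f_h`, `f_B` (NA for LCDs).
#' @export
sequence_table <- function(sticker_set = c("Y", "W", "F")) {
  lcds <- lapply(names(.lcd_sequences), build_lcd)
  ys <- lapply(ys_variant_names(), build_ys_variant)
  rows <- lapply(c(lcds, ys), function(s) {
    is_ys <- grepl("^[YS]+$", s$residues)
    data.frame(
      name = s$name, n = s$n,
      f_h = if (is_ys) hydrophobic_fraction(s, "Y")
            else hydrophobic_fraction(s, sticker_set),
      f_B = if (is_ys) blockiness(s)$f_B else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
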