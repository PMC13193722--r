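## In silico proteolysis: trypsin, GluC (two buffer modes), sequential
## trypsin->GluC, and the re-digest loss analysis used to explain why many
## tryptic 2HG peptides vanish after sequential digestion.

#' Define a protease cleavage rule
#'
#' Cleavage occurs after residue i exactly when residue i is in
#' `cleave_after` and residue i+1 is not in `suppress_before`.
#'
#' @param name Rule name.
#' @param cleave_after Residues cut C-terminally.
#' @param suppress_before Residues that block cleavage when next in sequence.
#' @return A `protease_rule`.
#' @export
protease_rule <- function(name, cleave_after, suppress_before = character()) {
  structure(list(name = name,
                 cleave_after = cleave_after,
                 suppress_before = suppress_before),
            class = "protease_rule")
}

#' @export
print.protease_rule <- function(x, ...) {
  cat("<protease> ", x$name, ": after [",
      paste(x$cleave_after, collapse = ""), "]",
      if (length(x$suppress_before) > 0)
        paste0(" except before [", paste(x$suppress_before, collapse = ""), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Trypsin rule
#'
#' Cuts after K/R; with `keil = TRUE` (default) cleavage before proline is
#' suppressed (Keil rule, the field-standard convention).
#'
#' @param keil Apply the proline suppression.
#' @return A `protease_rule`.
#' @export
trypsin <- function(keil = TRUE) {
  protease_rule("trypsin", c("K", "R"),
                if (keil) "P" else character())
}

#' GluC rule
#'
#' In bicarbonate buffer GluC cuts after Glu only; in phosphate buffer it
#' also cuts after Asp. Default is phosphate, matching a sequential
#' trypsin-then-GluC protocol run in phosphate buffer.
#'
#' @param buffer `"phosphate"` (E and D) or `"bicarbonate"` (E only).
#' @return A `protease_rule`.
#' @export
gluc <- function(buffer = c("phosphate", "bicarbonate")) {
  buffer <- match.arg(buffer)
  protease_rule(paste0("GluC-", buffer),
                if (buffer == "phosphate") c("E", "D") else "E")
}

#' Cleavage site positions
#'
#' @param sequence Protein/peptide sequence.
#' @param rule A `protease_rule`.
#' @return Integer positions i such that the bond i|i+1 is cut.
#' @export
cleavage_sites <- function(sequence, rule) {
  n <- nchar(sequence)
  if (n < 2) return(integer(0))
  chars <- strsplit(sequence, "")[[1]]
  which(chars[-n] %in% rule$cleave_after &
          !(chars[-1] %in% rule$suppress_before))
}

.peptide_df <- function(protein_id, start, end, sequence, missed_cleavages) {
  data.frame(protein_id = protein_id, start = as.integer(start),
             end = as.integer(end), sequence = sequence,
             missed_cleavages = as.integer(missed_cleavages),
             stringsAsFactors = FALSE)
}

.empty_peptide_df <- function() .peptide_df(character(0), integer(0),
                                            integer(0), character(0), integer(0))

#' Digest a sequence with one protease
#'
#' Emits all fully cleaved fragments plus every run of up to
#' `max_missed + 1` adjacent fragments (missed cleavages), ordered by start
#' position then length. Coordinates are 1-based inclusive on the parent.
#'
#' @param sequence Protein sequence.
#' @param rule A `protease_rule`.
#' @param max_missed Maximum missed cleavages (>= 0).
#' @param protein_id Identifier recorded in the output.
#' @return A data frame: protein_id, start, end, sequence, missed_cleavages.
#' @export
cleave <- function(sequence, rule, max_missed = 0L, protein_id = NA_character_) {
  stopifnot(max_missed >= 0)
  n <- nchar(sequence)
  if (n == 0) return(.empty_peptide_df())
  sites <- cleavage_sites(sequence, rule)
  b <- c(0L, sites, n)
  nfrag <- length(b) - 1L
  rows <- vector("list", 0)
  for (m in 0:min(max_missed, nfrag - 1L)) {
    j <- seq_len(nfrag - m)
    rows[[m + 1L]] <- .peptide_df(
      protein_id,
      b[j] + 1L,
      b[j + m + 1L],
      substring(sequence, b[j] + 1L, b[j + m + 1L]),
      m
    )
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE][, , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Sequential digestion with an ordered list of proteases
#'
#' Applies the first rule, then re-cleaves every product with the next,
#' composing coordinates back to the parent frame. Duplicate products
#' (same coordinates reachable through different missed-cleavage parents)
#' are merged; `missed_cleavages` is the number of internal cleavage sites
#' under the union of all rules.
#'
#' @param sequence Protein sequence.
#' @param rules List of `protease_rule`s, applied in order.
#' @param max_missed Integer vector, one value per rule (recycled).
#' @param protein_id Identifier recorded in the output.
#' @return A data frame as in [cleave()].
#' @export
sequential_digest <- function(sequence, rules = list(trypsin(), gluc()),
                              max_missed = c(2L, 2L),
                              protein_id = NA_character_) {
  stopifnot(length(rules) >= 1)
  max_missed <- rep_len(max_missed, length(rules))
  out <- cleave(sequence, rules[[1]], max_missed[1], protein_id)
  if (length(rules) > 1) {
    for (k in 2:length(rules)) {
      pieces <- lapply(seq_len(nrow(out)), function(i) {
        sub <- cleave(out$sequence[i], rules[[k]], max_missed[k], protein_id)
        sub$start <- sub$start + out$start[i] - 1L
        sub$end <- sub$end + out$start[i] - 1L
        sub
      })
      out <- do.call(rbind, pieces)
      out <- out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
    }
    # recompute missed cleavages against the union of sites on the parent
    union_sites <- sort(unique(unlist(lapply(rules, cleavage_sites,
                                             sequence = sequence))))
    out$missed_cleavages <- vapply(seq_len(nrow(out)), function(i) {
      sum(union_sites >= out$start[i] & union_sites <= out$end[i] - 1L)
    }, integer(1))
    out <- out[order(out$start, out$end), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' A peptide carrying site-indexed modifications
#'
#' @param sequence Peptide sequence.
#' @param mods List of `list(site = <1-based index within peptide>,
#'   spec = <modification_spec>)`.
#' @param protein_id,start,missed_cleavages Optional provenance.
#' @return A `peptide` object.
#' @export
peptide <- function(sequence, mods = list(), protein_id = NA_character_,
                    start = NA_integer_, missed_cleavages = NA_integer_) {
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) >= 1)
  if (length(mods) > 0) .validate_mods(sequence, mods)
  structure(list(sequence = sequence, mods = mods, protein_id = protein_id,
                 start = as.integer(start),
                 missed_cleavages = as.integer(missed_cleavages)),
            class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  lab <- x$sequence
  if (length(x$mods) > 0) {
    sites <- vapply(x$mods, function(m) m$site, numeric(1))
    chars <- strsplit(x$sequence, "")[[1]]
    lab <- paste0(lab, " [",
                  paste(sprintf("%s%d(%s)", chars[sites], sites,
                                vapply(x$mods, function(m) m$spec$name,
                                       character(1))),
                        collapse = ", "), "]")
  }
  cat("<peptide> ", lab, "\n", sep = "")
  invisible(x)
}

#' Modification sites of a peptide
#'
#' @param pep A `peptide`.
#' @return Integer vector of 1-based sites (empty if unmodified).
#' @export
mod_sites <- function(pep) {
  vapply(pep$mods, function(m) as.integer(m$site), integer(1))
}

#' Predict what re-digestion does to a modified peptide
#'
#' Re-cleaves a (tryptic) modified peptide with a second protease and
#' reports whether the modification-bearing fragment becomes too short to
#' identify (`lost_short`, default threshold < 7 residues) or loses all
#' basic residues K/R/H (`lost_basic`), the two mechanisms by which
#' sequential digestion drops modified peptides found with trypsin alone.
#'
#' @param pep A `peptide` with at least one modification.
#' @param rule Second protease (default GluC, phosphate buffer).
#' @param min_length Minimum identifiable fragment length.
#' @return A list: `lost_short`, `lost_basic`, and `fragments` (data frame
#'   with a `mod_sites` column giving remapped sites, comma-separated).
#' @export
predict_redigest_loss <- function(pep, rule = gluc(), min_length = 7L) {
  stopifnot(inherits(pep, "peptide"))
  if (length(pep$mods) == 0) stop("peptide carries no modification")
  n <- nchar(pep$sequence)
  sites <- mod_sites(pep)
  if (any(sites < 1 | sites > n)) stop("mod site outside peptide")
  frags <- cleave(pep$sequence, rule, max_missed = 0L,
                  protein_id = pep$protein_id)
  frag_of <- function(s) which(frags$start <= s & frags$end >= s)
  mod_frag <- vapply(sites, frag_of, integer(1))
  frags$mod_sites <- vapply(seq_len(nrow(frags)), function(i) {
    loc <- sites[mod_frag == i] - frags$start[i] + 1L
    paste(loc, collapse = ",")
  }, character(1))
  bearing <- unique(mod_frag)
  has_basic <- function(s) grepl("[KRH]", s)
  lost_short <- any(nchar(frags$sequence[bearing]) < min_length)
  lost_basic <- any(!has_basic(frags$sequence[bearing]))
  list(lost_short = lost_short, lost_basic = lost_basic, fragments = frags)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write protein sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Digest a whole proteome
#'
#' @param proteome Named character vector of protein sequences.
#' @param rules,max_missed As in [sequential_digest()].
#' @return Combined peptide data frame.
#' @export
digest_proteome <- function(proteome, rules = list(trypsin(), gluc()),
                            max_missed = c(2L, 2L)) {
  ids <- names(proteome)
  if (is.null(ids)) ids <- paste0("protein", seq_along(proteome))
  out <- do.call(rbind, lapply(seq_along(proteome), function(i) {
    sequential_digest(proteome[[i]], rules, max_missed, protein_id = ids[i])
  }))
  rownames(out) <- NULL
  out
}
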