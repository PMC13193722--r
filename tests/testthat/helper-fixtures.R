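# Shared fixture builders; everything is generated in code.

# Small, fast simulation config for unit tests.
test_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_proteins = 10L,
               protein_length = c(120L, 240L), n_background = 200L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# Noiseless spectrum built directly from a peptide's theoretical ions.
# Loss peaks (both channels, at `loss_rel` of base) included on request.
exact_spectrum <- function(pep, id = "syn", heavy = FALSE, charges = 1L,
                           precursor_charge = 2L, include_losses = FALSE,
                           loss_rel = 0.1, rt = 30) {
  frag <- theoretical_fragments(pep, charges = charges,
                                include_losses = FALSE, heavy = heavy)
  mzs <- frag$mz
  ints <- rep(100, nrow(frag))
  if (include_losses && length(pep$mods) > 0) {
    lf <- theoretical_fragments(pep, charges = charges,
                                include_losses = TRUE, heavy = heavy)
    lf <- lf[lf$loss != "none", , drop = FALSE]
    mzs <- c(mzs, lf$mz)
    ints <- c(ints, rep(100 * loss_rel, nrow(lf)))
  }
  prec <- precursor_descriptor(pep, precursor_charge, heavy = heavy)
  spectrum(id, prec$mz, precursor_charge, rt, mzs, ints)
}

# Independent position-wise protein cutter used as a digestion oracle:
# tests every bond against every rule separately, then cuts at the union.
brute_force_digest <- function(sequence, rules) {
  n <- nchar(sequence)
  if (n == 0) return(character(0))
  chars <- strsplit(sequence, "")[[1]]
  cut <- logical(max(n - 1, 0))
  for (i in seq_len(n - 1)) {
    for (r in rules) {
      if (chars[i] %in% r$cleave_after &&
          !(chars[i + 1] %in% r$suppress_before)) {
        cut[i] <- TRUE
      }
    }
  }
  bounds <- c(0, which(cut), n)
  vapply(seq_len(length(bounds) - 1),
         function(k) substr(sequence, bounds[k] + 1, bounds[k + 1]),
         character(1))
}

random_protein <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}
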