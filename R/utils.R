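# internal helpers shared across modules

# reverse complement; handles multi-base alleles
.revcomp <- function(a) {
  flipped <- chartr("ACGT", "TGCA", a)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

.is_palindromic <- function(ea, oa) ea == .revcomp(oa)

# two-sided normal p from an estimate and its SE; clamped into (0, 1]
.z_pvalue <- function(beta, se) {
  p <- 2 * stats::pnorm(-abs(beta / se))
  pmax(p, .Machine$double.xmin)
}

# derive a deterministic substream seed below 2^31 from a base seed and label
.substream <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.numeric(seed) * 7919 + h) %% 2147483629
}

.msg <- function(fmt, ..., verbose = TRUE) {
  if (verbose) message(sprintf(fmt, ...))
  invisible(NULL)
}
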