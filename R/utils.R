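# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(...) stop(..., call. = FALSE)

# order rows of a variant table by (chrom, pos); numeric chromosomes first
# in karyotype order, then the rest alphabetically
order_chrom_pos <- function(chrom, pos) {
  num <- suppressWarnings(as.numeric(sub("^chr", "", chrom)))
  key <- ifelse(is.na(num), Inf, num)
  order(key, chrom, pos)
}

# strand-ambiguous allele pair (A/T or C/G): indistinguishable across strands
is_ambiguous_pair <- function(ref, alt) {
  pair <- paste(pmin(toupper(ref), toupper(alt)),
                pmax(toupper(ref), toupper(alt)))
  pair %in% c("A T", "C G")
}

split_csv_field <- function(x) {
  out <- strsplit(as.character(x), ",", fixed = TRUE)
  lapply(out, function(v) {
    v <- trimws(v)
    v[nzchar(v) & !is.na(v)]
  })
}

join_csv_field <- function(v) paste(unique(v), collapse = ",")
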