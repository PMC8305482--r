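# File formats.  All tables are tab-separated UTF-8 with a header line;
# '#'-prefixed comment lines are allowed.  Coordinates are 1-based closed
# everywhere inside the package; BED is converted at the boundary.

summary_stat_columns <- c("variant_id", "chrom", "pos", "ref", "alt",
                          "effect_allele", "beta", "p_value", "eaf")

read_tsv_chr <- function(path) {
  if (!file.exists(path)) abort("input file not found: ", path)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE,
                    na.strings = c("NA", ""))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

num_col <- function(df, col, kind = "numeric") {
  raw <- df[[col]]
  out <- suppressWarnings(if (kind == "integer") as.integer(raw)
                          else as.numeric(raw))
  bad <- which(!is.na(raw) & is.na(out))
  if (length(bad))
    abort("unparseable ", kind, " in column '", col, "' at data row ",
          bad[1], ": '", raw[bad[1]], "'")
  out
}

#' Read GWAS summary statistics
#'
#' Reads a tab-separated table with header columns `variant_id, chrom, pos,
#' ref, alt, effect_allele, beta, p_value, eaf` (and optional `trait_id`).
#' `beta` is the natural-log odds ratio per copy of the effect allele.
#' Rows violating the record invariants (position >= 1, p-value in (0, 1],
#' effect-allele frequency in (0, 1), effect allele one of ref/alt, finite
#' beta) are rejected with their row number, as are duplicated variant ids.
#'
#' @param path Path to the TSV file.
#' @return A data frame of variant records, one per input row, in file order.
#' @export
read_summary_stats <- function(path) {
  df <- read_tsv_chr(path)
  missing <- setdiff(summary_stat_columns, names(df))
  if (length(missing))
    abort("summary-stats format error: missing required column(s): ",
          paste(missing, collapse = ", "))
  out <- data.frame(variant_id = df$variant_id,
                    chrom = df$chrom,
                    pos = num_col(df, "pos", "integer"),
                    ref = toupper(df$ref),
                    alt = toupper(df$alt),
                    effect_allele = toupper(df$effect_allele),
                    beta = num_col(df, "beta"),
                    p_value = num_col(df, "p_value"),
                    eaf = num_col(df, "eaf"),
                    trait_id = if ("trait_id" %in% names(df))
                      df$trait_id else NA_character_,
                    stringsAsFactors = FALSE)
  validate_variants(out)
  out
}

validate_variants <- function(v) {
  check <- function(bad, msg) {
    i <- which(bad)
    if (length(i)) abort("summary-stats row ", i[1], " (", v$variant_id[i[1]],
                         "): ", msg)
  }
  check(is.na(v$variant_id) | !nzchar(v$variant_id), "empty variant_id")
  check(is.na(v$chrom) | !nzchar(v$chrom), "empty chrom")
  check(is.na(v$pos) | v$pos < 1, "pos must be >= 1")
  check(is.na(v$p_value) | v$p_value <= 0 | v$p_value > 1,
        "p_value must be in (0, 1]")
  check(is.na(v$eaf) | v$eaf <= 0 | v$eaf >= 1, "eaf must be in (0, 1)")
  check(!is.finite(v$beta), "beta must be finite")
  check(v$effect_allele != v$ref & v$effect_allele != v$alt,
        "effect_allele must equal ref or alt")
  dup <- duplicated(v$variant_id)
  if (any(dup))
    abort("summary-stats row ", which(dup)[1], ": duplicate variant_id '",
          v$variant_id[which(dup)[1]], "'")
  invisible(v)
}

#' Write GWAS summary statistics
#'
#' Inverse of [read_summary_stats()]; a written table reads back to
#' identical records.
#'
#' @param variants Variant data frame as returned by [read_summary_stats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(variants, path) {
  cols <- c(summary_stat_columns, "trait_id")
  write_tsv(variants[, intersect(cols, names(variants)), drop = FALSE], path)
}

#' Read a BED interval file
#'
#' BED input is 0-based half-open; intervals are converted to the package's
#' internal 1-based closed convention (`start + 1`, `end`).  A tissue tag is
#' attached to every interval.  Zero- or negative-length intervals are
#' rejected with their row number.
#'
#' @param path Path to a BED3+ file (whitespace-separated, no header).
#' @param tissue Tissue label attached to all intervals (e.g. `"brain"`).
#' @return A data frame with columns `chrom, start, end, label, tissue`
#'   (1-based closed coordinates).
#' @export
read_bed <- function(path, tissue = NA_character_) {
  if (!file.exists(path)) abort("input file not found: ", path)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), label = character(),
                      tissue = character(), stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  df <- utils::read.table(path, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "#",
                          fill = TRUE)
  if (nrow(df) == 0) return(empty)
  if (ncol(df) < 3) abort("BED format error: fewer than 3 columns")
  start0 <- suppressWarnings(as.integer(df[[2]]))
  end0 <- suppressWarnings(as.integer(df[[3]]))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad)) abort("BED row ", bad[1], ": non-integer coordinates")
  bad <- which(end0 <= start0 | start0 < 0)
  if (length(bad))
    abort("BED row ", bad[1], ": end must exceed start (0-based half-open)")
  fallback <- paste0(df[[1]], ":", start0 + 1L, "-", end0)
  label <- if (ncol(df) >= 4) {
    given <- df[[4]]
    ifelse(is.na(given) | !nzchar(given), fallback, given)
  } else fallback
  data.frame(chrom = df[[1]], start = start0 + 1L, end = end0,
             label = label, tissue = tissue, stringsAsFactors = FALSE)
}

#' Write intervals as BED
#'
#' Converts from internal 1-based closed back to 0-based half-open;
#' [read_bed()] of the result is the identity.
#'
#' @param intervals Interval data frame (`chrom, start, end, label`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(intervals$chrom, intervals$start - 1L, intervals$end,
                   intervals$label)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read effect-allele dosages from a VCF
#'
#' Extracts GT fields from a plain-text (or bgzipped) VCF and converts each
#' genotype to a count of the effect allele in \[0, 2\].  When the effect
#' allele is the VCF REF, the dosage is `2 - (ALT count)`.  Missing
#' genotypes become `NA` (later mean-imputed by [compute_prs()]).
#' Multiallelic records and variants absent from `effect_alleles` are
#' skipped with a warning tally.
#'
#' @param path Path to the VCF.
#' @param effect_alleles Named character vector mapping variant id to its
#'   effect allele.
#' @return A numeric samples x variants matrix with dimnames; entries in
#'   \[0, 2\] or `NA`.
#' @export
read_vcf_dosages <- function(path, effect_alleles) {
  if (!file.exists(path)) abort("input file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  known <- ids %in% names(effect_alleles)
  n_multi <- sum(multi)
  n_unknown <- sum(!known & !multi)
  if (n_multi) warning(n_multi, " multiallelic record(s) skipped")
  if (n_unknown) warning(n_unknown,
                         " record(s) without an effect allele skipped")
  keep <- which(!multi & known)
  gt <- vcfR::extract.gt(v)
  samples <- colnames(gt)
  dos <- matrix(NA_real_, nrow = length(samples), ncol = length(keep),
                dimnames = list(samples, ids[keep]))
  for (k in seq_along(keep)) {
    i <- keep[k]
    g <- gt[i, ]
    alleles <- strsplit(as.character(g), "[/|]")
    altc <- vapply(alleles, function(a) {
      if (length(a) == 0 || anyNA(a) || any(a == ".")) return(NA_real_)
      sum(a == "1")
    }, numeric(1))
    eff <- toupper(effect_alleles[[ids[i]]])
    if (eff == toupper(fix[i, "ALT"])) {
      dos[, k] <- altc
    } else if (eff == toupper(fix[i, "REF"])) {
      dos[, k] <- 2 - altc
    } else {
      abort("effect allele '", eff, "' for ", ids[i],
            " matches neither REF nor ALT")
    }
  }
  dos
}

#' Write a dosage matrix as a plain-text VCF
#'
#' Emits diploid GT genotypes (`0/0`, `0/1`, `1/1`, `./.`) for integer
#' dosages of the ALT allele.  Companion writer for [read_vcf_dosages()];
#' round-trips exactly when the effect allele is ALT.
#'
#' @param dosages Samples x variants matrix of ALT-allele counts (0, 1, 2
#'   or `NA`).
#' @param variants Variant data frame supplying `variant_id, chrom, pos,
#'   ref, alt` for the matrix columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_dosages <- function(dosages, variants, path) {
  vid <- colnames(dosages)
  idx <- match(vid, variants$variant_id)
  if (anyNA(idx)) abort("variants table is missing ids present in dosages")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(dosages)),
                     collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (k in seq_along(vid)) {
    d <- dosages[, k]
    g <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    i <- idx[k]
    writeLines(paste(c(variants$chrom[i], variants$pos[i], vid[k],
                       variants$ref[i], variants$alt[i], ".", ".", ".",
                       "GT", g), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a curated gene table
#'
#' Columns: `gene_id, symbol, map_location, chromosome, span_start,
#' span_end, origin, protein_accessions` (accessions comma-separated,
#' possibly empty; spans may be empty when proximity mapping is not used).
#'
#' @param path Path to the TSV file.
#' @return A gene-record data frame.
#' @export
read_gene_table <- function(path) {
  df <- read_tsv_chr(path)
  req <- c("gene_id", "symbol", "map_location", "chromosome", "origin")
  missing <- setdiff(req, names(df))
  if (length(missing))
    abort("gene-table format error: missing column(s): ",
          paste(missing, collapse = ", "))
  bad <- !df$origin %in% c("common", "GenesAD", "ProteinsAD")
  if (any(bad))
    abort("gene-table row ", which(bad)[1], ": invalid origin '",
          df$origin[which(bad)[1]], "'")
  if (anyDuplicated(df$gene_id))
    abort("gene-table: duplicate gene_id '",
          df$gene_id[duplicated(df$gene_id)][1], "'")
  data.frame(gene_id = df$gene_id, symbol = df$symbol,
             map_location = df$map_location, chromosome = df$chromosome,
             span_start = if ("span_start" %in% names(df))
               num_col(df, "span_start", "integer") else NA_integer_,
             span_end = if ("span_end" %in% names(df))
               num_col(df, "span_end", "integer") else NA_integer_,
             origin = df$origin,
             protein_accessions = if ("protein_accessions" %in% names(df))
               ifelse(is.na(df$protein_accessions), "",
                      df$protein_accessions) else "",
             stringsAsFactors = FALSE)
}

#' Write a curated gene table
#' @param genes Gene-record data frame (see [read_gene_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  cols <- c("gene_id", "symbol", "map_location", "chromosome",
            "span_start", "span_end", "origin", "protein_accessions")
  write_tsv(genes[, intersect(cols, names(genes)), drop = FALSE], path)
}

#' Read a GWAS-catalog style variant-to-trait table
#'
#' @param path TSV with columns `variant_id, trait_id`.
#' @return A data frame with those two columns.
#' @export
read_catalog <- function(path) {
  df <- read_tsv_chr(path)
  missing <- setdiff(c("variant_id", "trait_id"), names(df))
  if (length(missing))
    abort("catalog format error: missing column(s): ",
          paste(missing, collapse = ", "))
  df[, c("variant_id", "trait_id")]
}

#' Read a variant-consequence table
#'
#' @param path TSV with columns `variant_id, gene_id, consequence,
#'   aa_change, ptm_site_hit`; consequence is one of `missense, synonymous,
#'   noncoding, other`.
#' @return A data frame with those columns (`ptm_site_hit` logical).
#' @export
read_consequences <- function(path) {
  df <- read_tsv_chr(path)
  req <- c("variant_id", "gene_id", "consequence")
  missing <- setdiff(req, names(df))
  if (length(missing))
    abort("consequence-table format error: missing column(s): ",
          paste(missing, collapse = ", "))
  ok <- c("missense", "synonymous", "noncoding", "other")
  bad <- !df$consequence %in% ok
  if (any(bad))
    abort("consequence-table row ", which(bad)[1],
          ": invalid consequence '", df$consequence[which(bad)[1]], "'")
  data.frame(variant_id = df$variant_id, gene_id = df$gene_id,
             consequence = df$consequence,
             aa_change = if ("aa_change" %in% names(df))
               df$aa_change else NA_character_,
             ptm_site_hit = if ("ptm_site_hit" %in% names(df))
               as.logical(df$ptm_site_hit) %in% TRUE else FALSE,
             stringsAsFactors = FALSE)
}

#' Read an eQTL table
#'
#' @param path TSV with columns `variant_id, gene_id, tissue`.
#' @return A data frame with those columns.
#' @export
read_eqtl <- function(path) {
  df <- read_tsv_chr(path)
  missing <- setdiff(c("variant_id", "gene_id", "tissue"), names(df))
  if (length(missing))
    abort("eQTL format error: missing column(s): ",
          paste(missing, collapse = ", "))
  df[, c("variant_id", "gene_id", "tissue")]
}
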