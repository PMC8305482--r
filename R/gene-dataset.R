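# Data fusion of gene- and protein-derived Alzheimer's gene lists, variant
# to gene mapping, missense flagging, and trait-severity set construction.

#' Merge gene- and protein-derived gene lists into one Origin-annotated table
#'
#' Fuses a gene-database list and a protein-database list (already
#' species-filtered, joined on `gene_id`) into a single non-redundant gene
#' table.  Each output record carries an `origin` field: `common` when the
#' gene appeared in both inputs, `GenesAD` when only in the gene list,
#' `ProteinsAD` when only in the protein list.  Protein accessions are
#' accumulated (comma-separated) on common and protein-only entries, so
#' `|output| = |gene-only| + |protein-only| + |intersection|`.
#'
#' @param gene_list Data frame with at least `gene_id`; recognised extras:
#'   `symbol, map_location, chromosome, span_start, span_end`.
#' @param protein_gene_list Data frame with `gene_id, protein_accession` and
#'   optionally `symbol, map_location, chromosome`.
#' @return A gene-record data frame (see [read_gene_table()] for columns).
#'   Duplicate ids within one input are deduplicated with a warning
#'   (attributes merged); a conflicting chromosome for the same gene across
#'   inputs is an error.
#' @export
merge_gene_protein_lists <- function(gene_list, protein_gene_list) {
  if (is.null(gene_list$gene_id))
    abort("gene_list must have a gene_id column")
  gl <- dedup_gene_rows(gene_list, "gene list")
  pl <- collapse_protein_rows(protein_gene_list)

  g_ids <- gl$gene_id
  p_ids <- pl$gene_id
  both <- intersect(g_ids, p_ids)

  # chromosome conflicts across inputs
  if (length(both) && !is.null(pl$chromosome)) {
    gi <- match(both, g_ids); pi <- match(both, p_ids)
    gc <- gl$chromosome[gi]; pc <- pl$chromosome[pi]
    conflict <- !is.na(gc) & !is.na(pc) & nzchar(gc) & nzchar(pc) & gc != pc
    if (any(conflict))
      abort("conflicting chromosome for gene '", both[which(conflict)[1]],
            "' across gene and protein lists")
  }

  field <- function(df, col, i, default = NA_character_) {
    if (!is.null(df[[col]])) df[[col]][i] else rep(default, length(i))
  }
  gi <- seq_along(g_ids)
  out_g <- data.frame(gene_id = g_ids,
                      symbol = field(gl, "symbol", gi),
                      map_location = field(gl, "map_location", gi),
                      chromosome = field(gl, "chromosome", gi),
                      span_start = as.integer(field(gl, "span_start", gi, NA)),
                      span_end = as.integer(field(gl, "span_end", gi, NA)),
                      origin = ifelse(g_ids %in% p_ids, "common", "GenesAD"),
                      protein_accessions = "",
                      stringsAsFactors = FALSE)
  pm <- match(out_g$gene_id, p_ids)
  hit <- !is.na(pm)
  out_g$protein_accessions[hit] <- pl$accessions[pm[hit]]

  only_p <- which(!p_ids %in% g_ids)
  np <- length(only_p)
  out_p <- data.frame(gene_id = p_ids[only_p],
                      symbol = field(pl, "symbol", only_p),
                      map_location = field(pl, "map_location", only_p),
                      chromosome = field(pl, "chromosome", only_p),
                      span_start = rep(NA_integer_, np),
                      span_end = rep(NA_integer_, np),
                      origin = rep("ProteinsAD", np),
                      protein_accessions = pl$accessions[only_p],
                      stringsAsFactors = FALSE)
  out <- rbind(out_g, out_p)
  rownames(out) <- NULL
  out
}

dedup_gene_rows <- function(df, what) {
  dup <- duplicated(df$gene_id)
  if (any(dup)) {
    warning(sum(dup), " duplicate gene_id(s) in ", what,
            " deduplicated (first occurrence kept)")
    df <- df[!dup, , drop = FALSE]
  }
  df
}

# one row per gene with comma-joined accessions
collapse_protein_rows <- function(df) {
  if (is.null(df) || nrow(df) == 0)
    return(data.frame(gene_id = character(), accessions = character(),
                      stringsAsFactors = FALSE))
  if (is.null(df$gene_id))
    abort("protein_gene_list must have a gene_id column")
  acc <- df$protein_accession %||% rep(NA_character_, nrow(df))
  ids <- unique(df$gene_id)
  i <- match(ids, df$gene_id)
  out <- data.frame(gene_id = ids,
                    accessions = vapply(ids, function(g) {
                      a <- acc[df$gene_id == g]
                      join_csv_field(a[!is.na(a) & nzchar(a)])
                    }, character(1)),
                    stringsAsFactors = FALSE)
  for (col in c("symbol", "map_location", "chromosome"))
    if (!is.null(df[[col]])) out[[col]] <- df[[col]][i]
  rownames(out) <- NULL
  out
}

#' Map variants to nearby genes
#'
#' A variant maps to a gene iff it lies on the same chromosome and its
#' position falls in `[span_start - window_bp, span_end + window_bp]`
#' (closed interval).  With `window_bp = 0` this is plain span overlap; the
#' mapping is monotone in the window (a larger window yields a superset).
#'
#' @param variants Variant data frame (`variant_id, chrom, pos`).
#' @param genes Gene-record data frame with non-missing spans.
#' @param window_bp Proximity window in base pairs (>= 0).
#' @return A named list: one character vector of gene ids per variant id
#'   (empty vector when the variant maps to nothing).
#' @export
map_snps_to_genes <- function(variants, genes, window_bp) {
  if (window_bp < 0) abort("window_bp must be >= 0")
  if (nrow(genes) && (anyNA(genes$span_start) || anyNA(genes$span_end)))
    abort("all genes must carry spans for proximity mapping")
  res <- rep(list(character(0)), nrow(variants))
  names(res) <- variants$variant_id
  for (j in seq_len(nrow(genes))) {
    hit <- which(variants$chrom == genes$chromosome[j] &
                 variants$pos >= genes$span_start[j] - window_bp &
                 variants$pos <= genes$span_end[j] + window_bp)
    for (i in hit) res[[i]] <- c(res[[i]], genes$gene_id[j])
  }
  res
}

#' Extract missense (amino-acid-changing) consequence rows
#'
#' Filters a consequence table down to the missense rows for the supplied
#' variants — the variants whose change substitutes an amino acid, carrying
#' the substitution (`aa_change`, "RefPosAlt") and the PTM-site flag
#' through unchanged.  Variants absent from the table are treated as
#' consequence `other` and drop out.
#'
#' @param variants Variant data frame (`variant_id`).
#' @param consequences Consequence data frame (see [read_consequences()]).
#' @return The missense subset of `consequences`.  A missense row without
#'   an `aa_change` is a data error.
#' @export
annotate_amino_acid_change <- function(variants, consequences) {
  sub <- consequences[consequences$variant_id %in% variants$variant_id &
                      consequences$consequence == "missense", , drop = FALSE]
  bad <- is.na(sub$aa_change) | !nzchar(sub$aa_change)
  if (any(bad))
    abort("missense row for variant '", sub$variant_id[which(bad)[1]],
          "' lacks aa_change")
  rownames(sub) <- NULL
  sub
}

#' Partition catalog variants into severity groups
#'
#' Splits the variants of two GWAS-catalog traits — a severe form (default
#' concept: Alzheimer's disease, EFO_0000249) and a milder form (late-onset
#' Alzheimer's disease, EFO_1001870) — into three pairwise-disjoint sets:
#' variants unique to the severe trait, variants unique to the mild trait,
#' and variants reported for both.  Rows for any other trait are ignored.
#'
#' @param catalog_rows Data frame with `variant_id, trait_id`.
#' @param severe_trait Trait id of the severe form.
#' @param mild_trait Trait id of the mild form (must differ).
#' @return An object of class `severity_sets`: a list with
#'   `severe_trait_id, mild_trait_id, severe_only, mild_only, both`.
#' @export
build_severity_sets <- function(catalog_rows,
                                severe_trait = "EFO_0000249",
                                mild_trait = "EFO_1001870") {
  if (identical(severe_trait, mild_trait))
    abort("severe_trait and mild_trait must be distinct")
  s <- unique(catalog_rows$variant_id[catalog_rows$trait_id == severe_trait])
  m <- unique(catalog_rows$variant_id[catalog_rows$trait_id == mild_trait])
  structure(list(severe_trait_id = severe_trait,
                 mild_trait_id = mild_trait,
                 severe_only = setdiff(s, m),
                 mild_only = setdiff(m, s),
                 both = intersect(s, m)),
            class = "severity_sets")
}

#' @export
print.severity_sets <- function(x, ...) {
  cat("Severity sets (severe:", x$severe_trait_id,
      "/ mild:", x$mild_trait_id, ")\n")
  cat(sprintf("  severe-only %d, mild-only %d, both %d\n",
              length(x$severe_only), length(x$mild_only), length(x$both)))
  invisible(x)
}

# severity group of each variant id given the sets
severity_group_of <- function(variant_ids, severity) {
  out <- rep("absent", length(variant_ids))
  out[variant_ids %in% severity$severe_only] <- "severe_only"
  out[variant_ids %in% severity$mild_only] <- "mild_only"
  out[variant_ids %in% severity$both] <- "both"
  out
}
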