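#' Annotate candidate regions with overlapping genes
#'
#' A gene is assigned to a region iff their half-open intervals share at
#' least 1 bp; strand is ignored. A gene overlapping several regions of one
#' direction appears once in that direction's deduplicated gene list.
#'
#' @param regions data.frame from [merge_regions()] (possibly several
#'   directions row-bound)
#' @param genes gene table from [read_gene_annotation()]
#' @return list with `regions` (input plus a `gene_ids` comma-separated
#'   column) and `genes_by_direction` (named list of sorted unique gene-id
#'   vectors)
#' @export
overlap_genes <- function(regions, genes) {
  if (nrow(regions) == 0L)
    return(list(regions = cbind(regions, gene_ids = character(0)),
                genes_by_direction = list()))
  missing_chrom <- setdiff(unique(regions$chrom), unique(genes$chrom))
  if (length(missing_chrom) > 0L)
    warning("no annotation for chromosome(s): ",
            paste(missing_chrom, collapse = ", "))
  all_chroms <- union(unique(regions$chrom), unique(genes$chrom))
  gr_regions <- GenomicRanges::GRanges(
    factor(regions$chrom, levels = all_chroms),
    IRanges::IRanges(regions$start + 1, regions$end))
  gr_genes <- GenomicRanges::GRanges(
    factor(genes$chrom, levels = all_chroms),
    IRanges::IRanges(genes$start + 1, genes$end))
  hits <- GenomicRanges::findOverlaps(gr_regions, gr_genes,
                                      ignore.strand = TRUE)
  ids_per_region <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
                          factor(S4Vectors::queryHits(hits),
                                 levels = seq_len(nrow(regions))))
  regions$gene_ids <- vapply(ids_per_region, function(g)
    paste(sort(unique(g)), collapse = ","), "")
  by_dir <- lapply(split(seq_len(nrow(regions)), regions$direction),
                   function(rows)
                     sort(unique(unlist(ids_per_region[rows], use.names = FALSE))))
  list(regions = regions, genes_by_direction = by_dir)
}

#' Hypergeometric gene-set enrichment
#'
#' For each gene set, tests over-representation of the candidate genes in
#' the set by the upper-tail hypergeometric probability P(X >= k) with
#' population size |universe|, success count |set ∩ universe| and draw count
#' |candidates|. Rows are sorted by p; FDR is Benjamini-Hochberg over all
#' tested sets.
#'
#' @param candidate_genes character vector; must be a subset of `universe`
#' @param gene_sets named list of character vectors (set id -> gene ids);
#'   each set is intersected with `universe` before testing
#' @param universe character vector of background gene ids
#' @return data.frame with columns `set_id`, `set_size`, `overlap`,
#'   `p_value`, `fdr`, sorted by `p_value`
#' @export
hypergeometric_enrichment <- function(candidate_genes, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty gene universe")
  candidate_genes <- unique(candidate_genes)
  outside <- setdiff(candidate_genes, universe)
  if (length(outside) > 0L)
    stop("candidate gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  n_univ <- length(universe)
  n_cand <- length(candidate_genes)
  rows <- lapply(names(gene_sets), function(sid) {
    set <- intersect(unique(gene_sets[[sid]]), universe)
    k <- length(intersect(set, candidate_genes))
    p <- stats::phyper(k - 1, length(set), n_univ - length(set), n_cand,
                       lower.tail = FALSE)
    data.frame(set_id = sid, set_size = length(set), overlap = k,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; input order is preserved on return.
#'
#' @param p_values numeric vector of p-values in (0, 1]
#' @return adjusted values, same length and order
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
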