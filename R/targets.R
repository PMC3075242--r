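#' Build a target-prediction set
#'
#' A per-source, per-species table of predicted miRNA-to-gene pairs, as
#' exported from any prediction database. Duplicate pairs collapse to one.
#'
#' @param pairs data.frame with columns `mirna` and `gene`
#' @param source prediction source name (e.g. "TargetScan")
#' @param species species label (e.g. "mouse")
#' @return data.frame of class `target_set` with attributes `source` and
#'   `species`
#' @export
target_set <- function(pairs, source = "unknown", species = "unknown") {
  stopifnot(all(c("mirna", "gene") %in% names(pairs)))
  pairs <- unique(data.frame(mirna = as.character(pairs$mirna),
                             gene = as.character(pairs$gene),
                             stringsAsFactors = FALSE))
  rownames(pairs) <- NULL
  structure(pairs, class = c("target_set", "data.frame"),
            source = source, species = species)
}

#' Read a prediction table from a delimited file
#' @param path file with columns `mirna`, `gene`
#' @param source,species labels attached to the set
#' @return a [target_set]
#' @export
read_target_set <- function(path, source = "unknown", species = "unknown") {
  target_set(utils::read.delim(path, sep = .delim_for(path),
                               stringsAsFactors = FALSE),
             source = source, species = species)
}

#' Cross-species conserved targets of each miRNA
#'
#' Keeps, per miRNA, the mouse genes predicted as targets in the mouse set
#' whose mapped human ortholog is predicted as a target of the same miRNA in
#' the human set. Mouse genes absent from the ortholog map are dropped (the
#' count is attached as attribute `n_unmapped`); a one-to-many mapping keeps
#' the gene if any mapped counterpart is predicted.
#'
#' @param mouse,human [target_set] (or plain data.frame) of pairs from the
#'   same source
#' @param orthologs data.frame with columns `mouse_id`, `human_id`
#' @return `target_set`-like data.frame (mirna, gene) of conserved pairs in
#'   mouse gene ids, with attribute `n_unmapped`
#' @export
conserved_targets <- function(mouse, human, orthologs) {
  stopifnot(all(c("mirna", "gene") %in% names(mouse)),
            all(c("mirna", "gene") %in% names(human)),
            all(c("mouse_id", "human_id") %in% names(orthologs)))
  mapped <- mouse$gene %in% orthologs$mouse_id
  n_unmapped <- length(unique(mouse$gene[!mapped]))
  mouse <- mouse[mapped, , drop = FALSE]
  hkey <- paste(human$mirna, human$gene, sep = "\r")
  # one-to-many: a mouse gene survives if any ortholog is predicted
  keep <- vapply(seq_len(nrow(mouse)), function(i) {
    counterparts <- orthologs$human_id[orthologs$mouse_id == mouse$gene[i]]
    any(paste(mouse$mirna[i], counterparts, sep = "\r") %in% hkey)
  }, logical(1))
  out <- unique(mouse[keep, c("mirna", "gene"), drop = FALSE])
  rownames(out) <- NULL
  structure(out, class = c("target_set", "data.frame"),
            source = attr(mouse, "source"), species = "conserved",
            n_unmapped = n_unmapped)
}

#' Pool per-source target predictions into a master list
#'
#' Union of pairs across sources, per miRNA, retaining provenance: each pair
#' lists the sources that predicted it.
#'
#' @param sets named list of conserved pair data.frames (mirna, gene)
#' @return data.frame: mirna, gene, sources (comma-separated), n_sources
#' @export
pool_sources <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1)
  if (is.null(names(sets))) names(sets) <- paste0("source", seq_along(sets))
  long <- do.call(rbind, lapply(names(sets), function(nm) {
    s <- unique(as.data.frame(sets[[nm]])[, c("mirna", "gene")])
    if (nrow(s)) s$src <- nm
    s
  }))
  if (is.null(long) || nrow(long) == 0) {
    return(data.frame(mirna = character(), gene = character(),
                      sources = character(), n_sources = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(long$mirna, long$gene, sep = "\r")
  agg <- tapply(long$src, key, function(s) paste(sort(unique(s)), collapse = ","))
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(mirna = vapply(parts, `[`, "", 1),
                    gene = vapply(parts, `[`, "", 2),
                    sources = unname(agg),
                    stringsAsFactors = FALSE)
  out$n_sources <- lengths(strsplit(out$sources, ","))
  out <- out[order(out$mirna, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Keep only targets expressed in the reference tissue
#'
#' Drops predicted targets whose gene was not scored `"Present"` in the
#' expression dataset. Genes missing from the call table count as Absent;
#' the number of such genes is attached as attribute `n_uncalled`.
#'
#' @param master pooled prediction data.frame with a `gene` column
#' @param present_calls named character vector gene -> "Present"/"Absent"
#' @return filtered data.frame with attribute `n_uncalled`
#' @export
expression_filter <- function(master, present_calls) {
  stopifnot("gene" %in% names(master))
  call <- unname(present_calls[master$gene])
  n_uncalled <- length(unique(master$gene[is.na(call)]))
  keep <- !is.na(call) & call == "Present"
  out <- master[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_uncalled") <- n_uncalled
  out
}

#' Right-tailed Fisher (hypergeometric) gene-set enrichment
#'
#' For each named gene set, the probability of observing at least the seen
#' overlap between the target list and the set under random draws from the
#' background: `p = P(X >= k)` with `X ~ Hypergeom(N, K, n)` where `N` is
#' the background size, `K` the set size within the background, `n` the
#' target-list size and `k` the observed overlap. Results are sorted by p.
#'
#' @param target_genes character vector of genes (must lie in `background`)
#' @param gene_sets named list of character vectors; each is intersected
#'   with the background
#' @param background the gene universe (typically the Present-call universe)
#' @return data.frame of class `enrichment_result`: set_name, k, K, n, N, p
#' @export
fisher_enrichment <- function(target_genes, gene_sets, background) {
  background <- unique(background)
  if (length(background) == 0) stop("empty background", call. = FALSE)
  target_genes <- unique(target_genes)
  stray <- setdiff(target_genes, background)
  if (length(stray)) {
    stop("target genes outside background: ",
         paste(utils::head(stray, 3), collapse = ", "), call. = FALSE)
  }
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  N <- length(background)
  n <- length(target_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), background)
    K <- length(set)
    k <- length(intersect(target_genes, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$set_name), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then gene ids.
#'
#' @param path GMT file
#' @return named list of character vectors
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[`, "", 1))
}

#' Full target-consensus workflow
#'
#' Per source, retain cross-species conserved targets; pool the sources into
#' a master list with provenance; drop targets not expressed
#' (`Present`-called) in the reference tissue.
#'
#' @param mouse,human named lists of per-source prediction data.frames
#' @param orthologs ortholog map (mouse_id, human_id)
#' @param present_calls named vector gene -> "Present"/"Absent"
#' @param order `"conserve_then_pool"` (default, per-source conservation)
#'   or `"pool_then_conserve"` (conservation on the pooled lists)
#' @return data.frame: mirna, gene, sources, n_sources (expressed, conserved
#'   targets)
#' @export
target_consensus <- function(mouse, human, orthologs, present_calls,
                             order = c("conserve_then_pool", "pool_then_conserve")) {
  order <- match.arg(order)
  stopifnot(identical(sort(names(mouse)), sort(names(human))))
  if (order == "conserve_then_pool") {
    cons <- lapply(names(mouse), function(src) {
      conserved_targets(mouse[[src]], human[[src]], orthologs)
    })
    names(cons) <- names(mouse)
    master <- pool_sources(cons)
  } else {
    mpool <- pool_sources(mouse)
    hpool <- pool_sources(human)
    master <- conserved_targets(mpool[c("mirna", "gene")],
                                hpool[c("mirna", "gene")], orthologs)
    master <- pool_sources(list(pooled = master))
  }
  expression_filter(master, present_calls)
}
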