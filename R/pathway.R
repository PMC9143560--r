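#' Read pathway sets from a GMT file
#'
#' One pathway per line: id, description, then tab-separated member ids.
#' Duplicated members within a set are removed with a warning. An optional
#' directory of per-pathway edge lists (`<id>.tsv`, two tab-separated
#' columns, source and target metabolite) attaches a directed reaction graph
#' to each pathway; edges referencing metabolites outside the member set are
#' an error.
#'
#' @param path GMT file path.
#' @param edges_dir optional directory of per-pathway edge-list files.
#' @return A named list of `pathway_set` objects (`id`, `name`, `members`,
#'   `graph` — an igraph or `NULL`).
#' @export
read_pathways <- function(path, edges_dir = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("malformed GMT line ", i, ": expected id, description and >= 1 member")
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warning("duplicate members in pathway '", fields[1], "' deduplicated")
      members <- unique(members)
    }
    graph <- NULL
    if (!is.null(edges_dir)) {
      ef <- file.path(edges_dir, paste0(fields[1], ".tsv"))
      if (file.exists(ef)) {
        edges <- read.delim(ef, header = FALSE, stringsAsFactors = FALSE)
        unknown <- setdiff(unique(unlist(edges[, 1:2])), members)
        if (length(unknown))
          stop("edge list for '", fields[1], "' references unknown nodes: ",
               paste(unknown, collapse = ", "))
        graph <- igraph::graph_from_data_frame(edges[, 1:2], directed = TRUE,
                                               vertices = members)
      }
    }
    structure(list(id = fields[1], name = fields[2], members = members,
                   graph = graph), class = "pathway_set")
  })
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` that a random selection of `n`
#' metabolites from a universe of `N` would hit at least the observed `k`
#' members of a pathway of (universe-mapped) size `K`.
#'
#' @param selected character vector of selected metabolite ids (must be a
#'   subset of `universe`).
#' @param pathway a `pathway_set` (or a character vector of members).
#' @param universe the background metabolite set.
#' @return Raw p-value.
#' @export
ora_test <- function(selected, pathway, universe) {
  members <- if (inherits(pathway, "pathway_set")) pathway$members else pathway
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  if (!all(selected %in% universe))
    stop("selected metabolites must be a subset of the universe")
  selected <- unique(selected)
  K <- length(intersect(members, universe))
  n <- length(selected)
  k <- length(intersect(selected, intersect(members, universe)))
  phyper(k - 1, K, length(universe) - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjusted values with monotonicity enforcement; order-equivariant.
#'
#' @param p_values raw p-values in `(0, 1]`.
#' @return Adjusted FDR values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Topology-based pathway impact
#'
#' The summed centrality of the matched (selected-and-in-pathway)
#' metabolites, normalized by the total centrality of all pathway
#' metabolites, giving a value in `[0, 1]`. Centrality is exact betweenness
#' (shortest-path counting on the directed reaction graph) or out-degree. If
#' the graph carries no centrality at all (e.g. no intermediate vertices),
#' the fraction of matched nodes is returned so the normalization contract
#' (all matched = 1, none = 0) still holds.
#'
#' @param pathway a `pathway_set` with a graph.
#' @param matched metabolite ids matched to the pathway.
#' @param mode `"betweenness"` (default) or `"out_degree"`.
#' @return Impact in `[0, 1]`, or `NA` when the pathway has no graph.
#' @export
pathway_impact <- function(pathway, matched, mode = c("betweenness", "out_degree")) {
  mode <- match.arg(mode)
  g <- pathway$graph
  if (is.null(g)) return(NA_real_)
  cent <- switch(mode,
                 betweenness = igraph::betweenness(g, directed = TRUE),
                 out_degree = igraph::degree(g, mode = "out"))
  matched <- intersect(matched, igraph::V(g)$name)
  total <- sum(cent)
  if (total == 0) return(length(matched) / igraph::vcount(g))
  sum(cent[matched]) / total
}

#' Pathway over-representation analysis of a selected metabolite set
#'
#' Runs [ora_test()] for every pathway against the harmonized universe,
#' adjusts with [bh_fdr()], computes [pathway_impact()] where a graph is
#' available, and sorts by FDR.
#'
#' @param selected selected metabolite ids.
#' @param pathways list of `pathway_set`s (see [read_pathways()]).
#' @param universe background metabolite set (conventionally the harmonized,
#'   pathway-mappable metabolites).
#' @param impact_mode passed to [pathway_impact()].
#' @return A data.frame of class `ora_result`, one row per pathway:
#'   `pathway`, `name`, `N`, `K`, `n`, `k`, `p`, `fdr`, `impact`.
#' @export
ora_analysis <- function(selected, pathways, universe,
                         impact_mode = "betweenness") {
  universe <- unique(universe)
  selected <- unique(intersect(selected, universe))
  rows <- lapply(pathways, function(pw) {
    members <- intersect(pw$members, universe)
    k_hits <- intersect(selected, members)
    data.frame(
      pathway = pw$id, name = pw$name,
      N = length(universe), K = length(members),
      n = length(selected), k = length(k_hits),
      p = ora_test(selected, pw, universe),
      impact = pathway_impact(pw, k_hits, mode = impact_mode),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out <- out[order(out$fdr, out$p), c("pathway", "name", "N", "K", "n", "k",
                                      "p", "fdr", "impact")]
  rownames(out) <- NULL
  structure(out, class = c("ora_result", "data.frame"))
}

#' Write ORA results to TSV
#'
#' @param ora an `ora_result`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_ora_tsv <- function(ora, path) {
  write.table(as.data.frame(ora), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
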