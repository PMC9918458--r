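# Interaction-network stage: map signature genes into a user-supplied
# protein-protein interaction edge list (STRING-export-like), extract the
# disease gene module as the largest connected component, and test the
# association between signature class and module sub-cluster.

#' Read a STRING-style edge list
#'
#' Expects a TSV with two gene columns and an optional numeric confidence
#' score in `[0, 1]`; header optional (detected when the first row's third
#' field is non-numeric or the first two fields are `gene_a`/`gene_b`-like).
#' Self-loops are dropped and duplicate undirected pairs collapsed keeping
#' the maximum score. Malformed rows are rejected with their line number.
#'
#' @param path TSV file path.
#' @return Data frame with `gene_a`, `gene_b`, `score`.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(data.frame(gene_a = character(), gene_b = character(),
                                        score = numeric(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  f1 <- fields[[1]]
  if (length(f1) >= 3 && is.na(suppressWarnings(as.numeric(f1[3])))) start <- 2L
  else if (length(f1) == 2 && tolower(f1[1]) %in% c("gene_a", "genea", "protein1", "node1")) start <- 2L
  rows <- vector("list", length(lines))
  for (i in seq(start, length.out = length(lines) - start + 1L)) {
    f <- fields[[i]]
    if (length(f) < 2 || any(f[1:2] == ""))
      stop("malformed edge row at line ", i)
    score <- if (length(f) >= 3) suppressWarnings(as.numeric(f[3])) else 1
    if (is.na(score)) stop("malformed score at line ", i)
    rows[[i]] <- data.frame(gene_a = f[1], gene_b = f[2], score = score,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  normalize_edges(out)
}

# drop self loops, collapse duplicate undirected pairs (max score wins)
normalize_edges <- function(edges) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(edges)))
  if (is.null(edges$score)) edges$score <- 1
  edges <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]
  if (!nrow(edges)) return(edges)
  key <- ifelse(edges$gene_a < edges$gene_b,
                paste(edges$gene_a, edges$gene_b, sep = "\r"),
                paste(edges$gene_b, edges$gene_a, sep = "\r"))
  ord <- order(key, -edges$score)
  edges <- edges[ord, , drop = FALSE]
  edges <- edges[!duplicated(key[ord]), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Map genes onto an interaction network
#'
#' Filters the edge list at a confidence cutoff, then induces the subgraph
#' on the query genes that appear in the filtered network. Genes absent from
#' the filtered network are reported separately as unmapped.
#'
#' @param genes Character vector of query gene ids.
#' @param edges Edge data frame (`gene_a`, `gene_b`, optional `score`).
#' @param min_score Minimum edge confidence kept (default 0.4, the STRING
#'   medium-confidence convention).
#' @return List with `graph` (igraph, induced subgraph), `mapped`
#'   (sorted gene ids present in the filtered network) and `unmapped`.
#' @export
map_to_network <- function(genes, edges, min_score = 0.4) {
  edges <- normalize_edges(edges)
  keep <- edges$score >= min_score
  edges <- edges[keep, , drop = FALSE]
  vertices <- unique(c(edges$gene_a, edges$gene_b))
  genes <- unique(genes)
  mapped <- sort(intersect(genes, vertices))
  unmapped <- sort(setdiff(genes, vertices))
  g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = vertices))
  sub <- igraph::induced_subgraph(g, vids = mapped)
  list(graph = sub, mapped = mapped, unmapped = unmapped)
}

#' Largest connected component of a gene subgraph
#'
#' Returns the disease gene module: the maximum-cardinality connected
#' component, with ties broken by the lexicographically smallest sorted
#' member list.
#'
#' @param graph An igraph undirected graph (as from [map_to_network()]).
#' @return List with `members` (sorted gene ids; empty for an empty graph)
#'   and `graph` (the induced component subgraph).
#' @export
largest_connected_component <- function(graph) {
  if (igraph::vcount(graph) == 0L)
    return(list(members = character(), graph = graph))
  comp <- igraph::components(graph)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  member_sets <- lapply(best, function(ci)
    sort(igraph::V(graph)$name[comp$membership == ci]))
  # lexicographic tie-break on the sorted member lists
  if (length(best) > 1L) {
    keys <- vapply(member_sets, paste, character(1), collapse = "\r")
    member_sets <- member_sets[order(keys)]
  }
  members <- member_sets[[1]]
  list(members = members,
       graph = igraph::induced_subgraph(graph, vids = members))
}

#' Fraction of mapped genes inside the module
#'
#' @param module Character vector of module member gene ids.
#' @param mapped_genes Character vector of mapped gene ids (superset of the
#'   module); must be non-empty.
#' @return Percentage rounded half-up to one decimal (e.g. 40/45 -> 88.9).
#' @export
module_fraction <- function(module, mapped_genes) {
  if (!length(mapped_genes)) stop("no mapped genes")
  if (!all(module %in% mapped_genes)) stop("module must be a subset of mapped genes")
  proportion_pct(length(unique(module)), length(unique(mapped_genes)), digits = 1)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Tests association between two binary annotations (e.g. signature class
#' vs module sub-cluster) by exact enumeration of tables with fixed margins,
#' summing the probabilities of tables no more likely than the observed one.
#'
#' @param table A 2x2 matrix of non-negative integer counts with positive
#'   row and column margins.
#' @return The two-sided p-value.
#' @export
cluster_association_test <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table))) stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) stop("zero margin")
  stats::fisher.test(table, alternative = "two.sided")$p.value
}
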