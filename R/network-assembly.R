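#' Normalize gene/protein symbols
#'
#' Uppercases, strips surrounding whitespace, and removes STRING-style
#' numeric species prefixes (e.g. `"9606.TP53"` becomes `"TP53"`), so
#' that PPI identifiers match gene symbols from association tables.
#'
#' @param x Character vector of raw symbols.
#' @return Character vector of normalized symbols.
#' @export
#' @examples
#' normalize_symbols(c(" tp53 ", "9606.VEGFA"))
normalize_symbols <- function(x) {
  x <- toupper(trimws(as.character(x)))
  sub("^[0-9]+\\.", "", x)
}

#' Read a gene-disease association table
#'
#' Reads a TSV export with columns `gene`, `disease_id`, `score` (a
#' DisGeNET-style GDA table) and returns the genes whose association
#' score is strictly greater than the cutoff. The default cutoff 0.01
#' keeps genes with score > 0.01.
#'
#' @param path Path to the TSV file (header required).
#' @param score_cutoff Strict lower cutoff on the GDA score, in [0, 1].
#' @param disease_id Optional disease identifier; when given, only rows
#'   for that disease are used.
#' @return Character vector of unique, normalized gene symbols.
#' @export
load_gda <- function(path, score_cutoff = 0.01, disease_id = NULL) {
  stopifnot(is.numeric(score_cutoff), score_cutoff >= 0, score_cutoff <= 1)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "score")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("GDA table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (!is.null(disease_id) && "disease_id" %in% names(tab)) {
    tab <- tab[tab$disease_id == disease_id, , drop = FALSE]
  }
  score <- suppressWarnings(as.numeric(tab$score))
  bad <- which(is.na(score))
  if (length(bad) > 0L) {
    stop("GDA table ", path, ": unparseable score in row ", bad[1L],
         " (gene ", tab$gene[bad[1L]], ")")
  }
  gene <- normalize_symbols(tab$gene)
  if (any(!nzchar(gene))) {
    stop("GDA table ", path, ": empty gene symbol in row ",
         which(!nzchar(gene))[1L])
  }
  unique(gene[score > score_cutoff])
}

#' Read a protein-protein interaction edge table
#'
#' Reads a STRING-style links export with columns `protein1`,
#' `protein2`, `combined_score` and keeps edges whose confidence is
#' strictly greater than the cutoff. STRING distributes confidence on
#' both a 0-1 and a 0-1000 scale; with `score_scale = "auto"` the whole
#' column is divided by 1000 whenever any value exceeds 1.
#'
#' Self-interactions are dropped with a warning; duplicate pairs are
#' collapsed to one edge (keeping the maximum confidence); endpoint
#' symbols are normalized and stored in lexicographic order.
#'
#' @param path Path to the TSV file.
#' @param confidence_cutoff Strict lower cutoff on the 0-1 confidence.
#' @param score_scale One of `"auto"`, `"unit"` (already 0-1), or
#'   `"thousand"` (divide by 1000).
#' @return A data frame with columns `protein_a`, `protein_b`,
#'   `confidence` (`protein_a < protein_b` lexicographically).
#' @export
load_ppi <- function(path, confidence_cutoff = 0.4,
                     score_scale = c("auto", "unit", "thousand")) {
  score_scale <- match.arg(score_scale)
  stopifnot(is.numeric(confidence_cutoff),
            confidence_cutoff >= 0, confidence_cutoff <= 1)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("protein1", "protein2", "combined_score")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("PPI table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  conf <- suppressWarnings(as.numeric(tab$combined_score))
  bad <- which(is.na(conf))
  if (length(bad) > 0L) {
    stop("PPI table ", path, ": unparseable combined_score in row ", bad[1L])
  }
  if (score_scale == "thousand" ||
      (score_scale == "auto" && any(conf > 1))) {
    conf <- conf / 1000
  }
  a <- normalize_symbols(tab$protein1)
  b <- normalize_symbols(tab$protein2)
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    stop("PPI table ", path, ": empty protein symbol")
  }
  self <- a == b
  if (any(self)) {
    warning("dropped ", sum(self), " self-interaction row(s) in ", path)
    a <- a[!self]; b <- b[!self]; conf <- conf[!self]
  }
  keep <- conf > confidence_cutoff
  a <- a[keep]; b <- b[keep]; conf <- conf[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  edges <- data.frame(protein_a = lo, protein_b = hi, confidence = conf,
                      stringsAsFactors = FALSE)
  if (nrow(edges) > 0L) {
    key <- paste(edges$protein_a, edges$protein_b, sep = "\t")
    best <- tapply(edges$confidence, key, max)
    first <- !duplicated(key)
    edges <- edges[first, , drop = FALSE]
    edges$confidence <- as.numeric(best[paste(edges$protein_a,
                                              edges$protein_b, sep = "\t")])
    edges <- edges[order(edges$protein_a, edges$protein_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  edges
}

#' Read a drug-target table
#'
#' Reads a TSV with columns `drug_id`, `target` (one row per pair) and
#' returns a named list of normalized target-symbol vectors, one per
#' drug.
#'
#' @param path Path to the TSV file.
#' @return Named list of character vectors (drug id -> target symbols).
#' @export
load_targets <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("drug_id", "target")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("drug-target table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  tg <- normalize_symbols(tab$target)
  sets <- lapply(split(tg, tab$drug_id), function(v) sort(unique(v)))
  if (any(lengths(sets) == 0L)) stop("drug with empty target set in ", path)
  sets
}

#' Read a gene-to-cluster membership table
#'
#' Reads a TSV with columns `gene`, `cluster` (a Metascape-style
#' GO-cluster membership export). A gene may belong to several
#' clusters.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `gene` (normalized), `cluster`.
#' @export
load_clusters <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "cluster")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("cluster table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  out <- data.frame(gene = normalize_symbols(tab$gene),
                    cluster = as.character(tab$cluster),
                    stringsAsFactors = FALSE)
  unique(out)
}

#' Build a disease network from genes and PPI edges
#'
#' Induces the subgraph of the (already cutoff-filtered) PPI edge list
#' on the given gene set. The result is a simple undirected graph.
#' Genes with no passing interaction are dropped, so the node count can
#' fall below the gene count, mirroring how a 685-gene association list
#' can yield a 636-node network. All non-isolated nodes are retained
#' whether or not they lie in the largest connected component; the
#' choice is recorded in the graph's `conventions` attribute.
#'
#' @param genes Character vector of gene symbols (normalized or raw).
#' @param edges Data frame with columns `protein_a`, `protein_b` (as
#'   returned by [load_ppi()]).
#' @return An [igraph][igraph::igraph-package] undirected graph.
#' @export
build_network <- function(genes, edges) {
  genes <- unique(normalize_symbols(genes))
  if (nrow(edges) == 0L) stop("no connected disease genes")
  keep <- edges$protein_a %in% genes & edges$protein_b %in% genes
  el <- edges[keep, c("protein_a", "protein_b"), drop = FALSE]
  if (nrow(el) == 0L) stop("no connected disease genes")
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  igraph::graph_attr(g, "conventions") <-
    "all non-isolated nodes retained (not restricted to largest component)"
  g
}

#' Write a network as a canonical edge-list TSV
#'
#' Two columns `protein_a`, `protein_b`; endpoints of each edge in
#' lexicographic order, rows sorted, so output is deterministic and a
#' written network re-reads identically.
#'
#' @param net An igraph graph.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  el <- igraph::as_edgelist(net)
  if (nrow(el) > 0L) {
    lo <- pmin(el[, 1L], el[, 2L]); hi <- pmax(el[, 1L], el[, 2L])
    el <- data.frame(protein_a = lo, protein_b = hi,
                     stringsAsFactors = FALSE)
    el <- el[order(el$protein_a, el$protein_b), , drop = FALSE]
  } else {
    el <- data.frame(protein_a = character(0), protein_b = character(0))
  }
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path Edge-list TSV path.
#' @return An igraph undirected graph.
#' @export
read_network <- function(path) {
  el <- utils::read.delim(path, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  igraph::simplify(g)
}
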