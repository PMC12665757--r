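# Residue-graph construction: each peptide becomes a chain graph with one
# node per residue token, bidirectional backbone edges, and a 7-channel node
# feature vector [hydrophobicity_z, charge_z, mol_weight_z, d_flag,
# lipid_flag, sin_pe, cos_pe]. The three physicochemical channels are
# z-scored with statistics pooled over all residues of the training set.

#' Fit feature normalization statistics
#'
#' Pools the hydrophobicity, side-chain charge and residue-mass values of
#' every residue across the training set and returns per-channel mean and
#' standard deviation. A degenerate (zero) standard deviation falls back to 1
#' so z-scoring stays defined.
#'
#' @param records Activity tibble (needs the `tokens` list-column) or a list
#'   of `pep_tokens`.
#' @param overrides Optional NSAA override tibble.
#' @return A `norm_stats` object: list with `mean` and `sd`, each length 3.
#' @export
fit_norm_stats <- function(records, overrides = NULL) {
  token_lists <- if (is.data.frame(records)) records$tokens else records
  if (length(token_lists) == 0) stop("empty training set", call. = FALSE)
  props <- lapply(token_lists, token_props, overrides = overrides)
  kd <- unlist(lapply(props, `[[`, "kd"))
  charge <- unlist(lapply(props, `[[`, "charge"))
  mass <- unlist(lapply(props, `[[`, "mass"))
  m <- c(kd = mean(kd), charge = mean(charge), mass = mean(mass))
  s <- c(kd = stats::sd(kd), charge = stats::sd(charge), mass = stats::sd(mass))
  s[!is.finite(s) | s == 0] <- 1
  structure(list(mean = m, sd = s, n_residues = length(kd)),
            class = "norm_stats")
}

#' @export
print.norm_stats <- function(x, ...) {
  cat("<norm_stats> fitted on", x$n_residues, "residues\n")
  print(rbind(mean = x$mean, sd = x$sd))
  invisible(x)
}

# Short deterministic fingerprint used to guard checkpoint/stats pairing
stats_fingerprint <- function(stats) {
  paste(sprintf("%.10g", c(stats$mean, stats$sd)), collapse = "|")
}

#' Per-residue node features
#'
#' @param tokens `pep_tokens` for the whole sequence.
#' @param stats Fitted `norm_stats`.
#' @param overrides Optional NSAA override tibble.
#' @return L x 7 numeric matrix; positions are 0-based in the sine/cosine
#'   encoding `sin(pi * pos / L)`, `cos(pi * pos / L)`.
#' @export
residue_features <- function(tokens, stats, overrides = NULL) {
  tokens <- as_tokens(tokens)
  p <- token_props(tokens, overrides)
  L <- length(tokens)
  pos <- seq_len(L) - 1
  cbind(
    hydrophobicity_z = (p$kd - stats$mean[["kd"]]) / stats$sd[["kd"]],
    charge_z = (p$charge - stats$mean[["charge"]]) / stats$sd[["charge"]],
    mol_weight_z = (p$mass - stats$mean[["mass"]]) / stats$sd[["mass"]],
    d_aa_flag = as.numeric(token_is_d(tokens)),
    lipid_flag = as.numeric(token_is_lipidated(tokens)),
    sin_pe = sin(pi * pos / L),
    cos_pe = cos(pi * pos / L)
  )
}

#' Build a peptide chain graph
#'
#' @param x Sequence string or `pep_tokens`.
#' @param stats Fitted `norm_stats`.
#' @param overrides Optional NSAA override tibble.
#' @return A `pep_graph`: list with `node_features` (L x 7), `edges`
#'   (2(L-1) x 2 integer matrix of directed src,dst pairs) and `length`.
#' @export
build_graph <- function(x, stats, overrides = NULL) {
  tokens <- as_tokens(x)
  L <- length(tokens)
  feats <- residue_features(tokens, stats, overrides)
  if (L > 1) {
    i <- seq_len(L - 1)
    edges <- rbind(cbind(i, i + 1L), cbind(i + 1L, i))
  } else {
    edges <- matrix(integer(0), ncol = 2)
  }
  colnames(edges) <- c("src", "dst")
  structure(list(node_features = feats, edges = edges, length = L),
            class = "pep_graph")
}

#' @export
print.pep_graph <- function(x, ...) {
  cat("<pep_graph>", x$length, "nodes,", nrow(x$edges), "directed edges\n")
  invisible(x)
}

#' Serialize a peptide graph to JSON
#'
#' Debug-oriented JSON form carrying nodes, edges and the fingerprint of the
#' normalization statistics the features were computed with.
#'
#' @param graph A `pep_graph`.
#' @param stats The `norm_stats` used to build it.
#' @param path Output path.
#' @export
write_graph_json <- function(graph, stats, path) {
  jsonlite::write_json(
    list(
      length = graph$length,
      node_features = graph$node_features,
      edges = graph$edges,
      stats_fingerprint = stats_fingerprint(stats)
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

# Pack a list of graphs into one batch: concatenated node matrix, offset
# edges (with self-loops appended for attention), and a graph-index vector.
batch_graphs <- function(graphs) {
  sizes <- vapply(graphs, `[[`, integer(1), "length")
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  X <- do.call(rbind, lapply(graphs, `[[`, "node_features"))
  edges <- do.call(rbind, purrr::map2(graphs, offsets, function(g, o) {
    if (nrow(g$edges) == 0) matrix(integer(0), ncol = 2) else g$edges + o
  }))
  n <- nrow(X)
  # self-loops let each node attend to itself
  edges <- rbind(edges, cbind(seq_len(n), seq_len(n)))
  ord <- order(edges[, 2], edges[, 1])
  edges <- edges[ord, , drop = FALSE]
  list(
    X = X,
    src = edges[, 1],
    dst = edges[, 2],
    graph_id = rep(seq_along(graphs), sizes),
    n_nodes = n,
    n_graphs = length(graphs)
  )
}
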