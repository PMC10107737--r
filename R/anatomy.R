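#' Canonical functional network labels
#'
#' The ten canonical networks used to summarise selected-edge anatomy:
#' medial frontal (MF), frontoparietal (FP), default mode (DMN), motor
#' (Mot), visual I/II (VisI, VisII), visual association (VAs), salience
#' (SAL), subcortical (SC) and cerebellar (CBL).
#'
#' @return Character vector of the ten labels, in display order.
#' @export
canonical_networks <- function() {
  c("MF", "FP", "DMN", "Mot", "VisI", "VisII", "VAs", "SAL", "SC", "CBL")
}

#' Consensus edges across cross-validation folds
#'
#' An edge belongs to the consensus of a tail if it was selected in
#' every fold (more generally, in at least `min_frequency` of folds).
#' Also returns the per-edge selection frequency for both tails.
#'
#' @param cv A `cpm_cv` from [run_loocv()].
#' @param min_frequency Minimum selection frequency for consensus
#'   membership; 1 = selected in every fold.
#' @return A `consensus_edges`: list with `positive` / `negative`
#'   (tibbles: `edge`, `i`, `j`, `node_i`, `node_j`, `frequency`),
#'   `frequency` (all ever-selected edges), `n_folds`, `n_nodes`,
#'   `node_ids`.
#' @export
consensus_edges <- function(cv, min_frequency = 1) {
  stopifnot(inherits(cv, "cpm_cv"), length(cv$folds) >= 1)
  stopifnot(min_frequency > 0, min_frequency <= 1)
  n_folds <- length(cv$folds)
  ei <- edge_index(cv$n_nodes, cv$node_ids)
  tail_tbl <- function(sign) {
    counts <- tabulate(unlist(lapply(cv$folds, `[[`, sign),
                              use.names = FALSE), nrow(ei))
    f <- counts / n_folds
    dplyr::mutate(ei[f > 0, ], frequency = f[f > 0], sign = sign)
  }
  pos <- tail_tbl("positive")
  neg <- tail_tbl("negative")
  structure(
    list(
      positive = dplyr::select(
        dplyr::filter(pos, .data$frequency >= min_frequency), -"sign"),
      negative = dplyr::select(
        dplyr::filter(neg, .data$frequency >= min_frequency), -"sign"),
      frequency = dplyr::bind_rows(pos, neg),
      n_folds = n_folds, min_frequency = min_frequency,
      n_nodes = cv$n_nodes, node_ids = cv$node_ids
    ),
    class = "consensus_edges"
  )
}

#' @export
print.consensus_edges <- function(x, ...) {
  total <- n_unique_edges(x$n_nodes)
  cat("Consensus edges over ", x$n_folds, " folds: ",
      nrow(x$positive), " positive (",
      signif(100 * nrow(x$positive) / total, 2), "%), ",
      nrow(x$negative), " negative (",
      signif(100 * nrow(x$negative) / total, 2), "%) of ", total,
      " edges\n", sep = "")
  invisible(x)
}

#' Binary mask matrix for one consensus tail
#'
#' @param ce A `consensus_edges`.
#' @param sign `"positive"` or `"negative"`.
#' @return Symmetric 0/1 matrix.
#' @export
consensus_mask <- function(ce, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  stopifnot(inherits(ce, "consensus_edges"))
  v <- numeric(n_unique_edges(ce$n_nodes))
  v[ce[[sign]]$edge] <- 1
  matrix_from_edges(v, ce$node_ids)
}

#' Node degree within a selected-edge mask
#'
#' Counts, per node, the unique selected edges incident to it, and sorts
#' descending (ties broken by ascending node label). Degrees obey the
#' handshake lemma: they sum to twice the unique-edge count.
#'
#' @param mask Symmetric binary matrix with zero diagonal.
#' @return Tibble: `node`, `degree`, sorted by decreasing degree.
#' @export
node_degree <- function(mask) {
  stopifnot(is.matrix(mask))
  if (!identical(mask, t(mask))) stop("mask is not symmetric", call. = FALSE)
  if (!all(mask %in% c(0, 1))) stop("mask must be binary", call. = FALSE)
  ids <- connectivity_node_ids(mask)
  deg <- rowSums(mask)
  tibble::tibble(node = ids, degree = as.integer(deg)) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$node)
}

#' Read a node-to-network assignment table
#'
#' @param path CSV with columns `node_id`, `network` (labels from
#'   [canonical_networks()]).
#' @return Tibble with character `node_id` and `network`.
#' @export
read_network_assignment <- function(path) {
  a <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  stopifnot(all(c("node_id", "network") %in% names(a)))
  validate_assignment(a)
}

validate_assignment <- function(assignment) {
  bad <- setdiff(unique(assignment$network), canonical_networks())
  if (length(bad)) {
    stop("unknown network label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(assignment$node_id)) {
    stop("node(s) mapped more than once: ",
         paste(unique(assignment$node_id[duplicated(assignment$node_id)]),
               collapse = ", "), call. = FALSE)
  }
  assignment
}

#' Random node-to-network assignment (synthetic fixture)
#'
#' Assigns nodes uniformly at random to the ten canonical networks — a
#' synthetic stand-in for a real atlas-to-network mapping, which is
#' dataset-specific and supplied as a file in practice.
#'
#' @param node_ids Node labels.
#' @param seed Seed.
#' @return Assignment tibble (`node_id`, `network`).
#' @export
random_assignment <- function(node_ids, seed = 1L) {
  set.seed(seed)
  tibble::tibble(
    node_id = as.character(node_ids),
    network = sample(canonical_networks(), length(node_ids),
                     replace = TRUE)
  )
}

#' Within/between-network edge-count matrix
#'
#' Summarises a selected-edge mask against the ten canonical networks:
#' entry (A, B) counts the unique selected edges with one end in network
#' A and the other in B; the diagonal counts within-network edges. The
#' total over unique entries equals the mask's unique-edge count.
#'
#' @param mask Symmetric binary matrix with node labels as dimnames.
#' @param assignment Assignment tibble (`node_id`, `network`).
#' @return A 10 x 10 symmetric integer matrix with
#'   [canonical_networks()] dimnames.
#' @export
canonical_matrix <- function(mask, assignment) {
  stopifnot(is.matrix(mask))
  if (!identical(mask, t(mask))) stop("mask is not symmetric", call. = FALSE)
  assignment <- validate_assignment(assignment)
  ids <- connectivity_node_ids(mask)
  nets <- canonical_networks()
  out <- matrix(0L, 10, 10, dimnames = list(nets, nets))
  sel <- which(mask != 0 & upper.tri(mask), arr.ind = TRUE)
  if (nrow(sel)) {
    map <- assignment$network[match(ids, assignment$node_id)]
    used <- unique(c(sel[, 1], sel[, 2]))
    if (anyNA(map[used])) {
      stop("node(s) without a network assignment: ",
           paste(ids[used][is.na(map[used])], collapse = ", "),
           call. = FALSE)
    }
    for (e in seq_len(nrow(sel))) {
      a <- map[sel[e, 1]]; b <- map[sel[e, 2]]
      out[a, b] <- out[a, b] + 1L
      if (a != b) out[b, a] <- out[b, a] + 1L
    }
  }
  out
}

#' Full anatomy summary of a consensus-edge result
#'
#' @param ce A `consensus_edges`.
#' @param assignment Assignment tibble covering the masked nodes.
#' @return An `anatomy_summary`: per-sign edge lists, degree tables and
#'   canonical 10x10 matrices.
#' @export
anatomy_summary <- function(ce, assignment) {
  stopifnot(inherits(ce, "consensus_edges"))
  out <- lapply(c(positive = "positive", negative = "negative"),
                function(sign) {
    m <- consensus_mask(ce, sign)
    list(edges = ce[[sign]], degree = node_degree(m),
         canonical = canonical_matrix(m, assignment))
  })
  structure(c(out, list(n_folds = ce$n_folds, n_nodes = ce$n_nodes)),
            class = "anatomy_summary")
}

#' Serialise an anatomy summary as CSV files
#'
#' @param summary An `anatomy_summary`.
#' @param dir Output directory.
#' @export
write_anatomy <- function(summary, dir) {
  stopifnot(inherits(summary, "anatomy_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sign in c("positive", "negative")) {
    readr::write_csv(summary[[sign]]$edges,
                     file.path(dir, paste0("edges_", sign, ".csv")))
    readr::write_csv(summary[[sign]]$degree,
                     file.path(dir, paste0("degree_", sign, ".csv")))
    utils::write.csv(summary[[sign]]$canonical,
                     file.path(dir, paste0("canonical_", sign, ".csv")))
  }
  invisible(dir)
}
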