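#' Build a driver-response network from an interaction table
#'
#' Assembles the mixed directed/undirected network used by all ranking
#' methods. Protein-protein interactions (`kind = "ppi"`) are undirected
#' and enter the activation matrix in both orientations; gene-regulatory
#' interactions (`kind = "regulatory"`) are directed regulator-to-target.
#' A gene and its protein product are a single vertex. Self-interactions
#' are removed and duplicate records are deduplicated silently.
#'
#' The activation matrix follows the convention `a[i, j] = 1` when vertex
#' `j` activates vertex `i`, i.e. a directed edge `source -> target` sets
#' `a[target, source] = 1`. The out-degree of `j` is the column sum
#' `d_j = sum_i a_ij`.
#'
#' @param interactions data frame with columns `source`, `target`, `kind`
#'   (`kind` in `"ppi"`, `"regulatory"`).
#' @param drivers character vector of driver gene symbols. Every driver
#'   must appear in at least one interaction.
#' @param responses character vector of response gene symbols. Responses
#'   that appear in no interaction are dropped with a warning (they are
#'   unconnected in the network model).
#'
#' @return An object of class `netpert_network`: a list with elements
#'   `vertices` (ordered symbols), `activation` (sparse matrix `a_ij`),
#'   `out_degree` (named vector `d_j`), `drivers`, `responses`, and
#'   `dropped_responses`.
#'
#' @examples
#' edges <- tibble::tibble(
#'   source = c("Tf1", "A"), target = c("A", "B"),
#'   kind = c("regulatory", "ppi")
#' )
#' net <- build_network(edges, drivers = "Tf1", responses = "B")
#' net$out_degree
#' @export
build_network <- function(interactions, drivers, responses) {
  interactions <- validate_interactions(interactions)
  drivers <- as.character(drivers)
  responses <- as.character(responses)
  if (length(drivers) == 0L) stop("at least one driver is required")
  if (length(responses) == 0L) stop("at least one response gene is required")

  # self-interactions removed
  interactions <- dplyr::filter(interactions, .data$source != .data$target)
  if (nrow(interactions) == 0L) stop("no interactions left after removing self-interactions")

  vertices <- sort(unique(c(interactions$source, interactions$target)))

  missing_drivers <- setdiff(drivers, vertices)
  if (length(missing_drivers) > 0L) {
    stop("driver(s) absent from the interaction network: ",
         paste(missing_drivers, collapse = ", "))
  }
  dropped <- setdiff(responses, vertices)
  if (length(dropped) > 0L) {
    warning(length(dropped), " response gene(s) unconnected in the network, dropped: ",
            paste(dropped, collapse = ", "))
  }
  responses <- intersect(responses, vertices)
  if (length(responses) == 0L) stop("no response gene is connected in the network")
  overlap <- intersect(drivers, responses)
  if (length(overlap) > 0L) {
    stop("drivers and responses must be disjoint; overlap: ",
         paste(overlap, collapse = ", "))
  }

  idx <- stats::setNames(seq_along(vertices), vertices)
  src <- idx[interactions$source]
  tgt <- idx[interactions$target]
  is_ppi <- interactions$kind == "ppi"

  # directed pairs (j activates i): regulatory source->target, ppi both ways
  i_all <- c(tgt, src[is_ppi])
  j_all <- c(src, tgt[is_ppi])
  keep <- !duplicated(cbind(i_all, j_all))
  activation <- Matrix::sparseMatrix(
    i = i_all[keep], j = j_all[keep], x = 1,
    dims = c(length(vertices), length(vertices)),
    dimnames = list(vertices, vertices)
  )

  out_degree <- Matrix::colSums(activation)
  names(out_degree) <- vertices

  structure(
    list(
      vertices = vertices,
      activation = activation,
      out_degree = out_degree,
      drivers = drivers,
      responses = responses,
      dropped_responses = dropped
    ),
    class = "netpert_network"
  )
}

validate_interactions <- function(interactions) {
  if (!is.data.frame(interactions)) stop("`interactions` must be a data frame")
  required <- c("source", "target", "kind")
  missing_cols <- setdiff(required, names(interactions))
  if (length(missing_cols) > 0L) {
    stop("`interactions` is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  interactions <- tibble::as_tibble(interactions)[required]
  interactions$source <- as.character(interactions$source)
  interactions$target <- as.character(interactions$target)
  interactions$kind <- as.character(interactions$kind)
  bad <- which(!interactions$kind %in% c("ppi", "regulatory"))
  if (length(bad) > 0L) {
    stop("unknown interaction kind at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         ": expected 'ppi' or 'regulatory'")
  }
  incomplete <- which(is.na(interactions$source) | is.na(interactions$target) |
                        interactions$source == "" | interactions$target == "")
  if (length(incomplete) > 0L) {
    stop("missing gene symbol at row(s) ",
         paste(utils::head(incomplete, 5L), collapse = ", "))
  }
  interactions
}

#' @export
print.netpert_network <- function(x, ...) {
  cat("<netpert_network> ", length(x$vertices), " vertices, ",
      Matrix::nnzero(x$activation), " directed activation entries\n", sep = "")
  cat("  drivers:  ", paste(x$drivers, collapse = ", "), "\n", sep = "")
  cat("  responses: ", length(x$responses), " connected",
      if (length(x$dropped_responses) > 0L)
        paste0(" (", length(x$dropped_responses), " dropped)"),
      "\n", sep = "")
  invisible(x)
}

vertex_index <- function(network, symbols) {
  idx <- match(symbols, network$vertices)
  if (anyNA(idx)) {
    stop("unknown vertex symbol(s): ",
         paste(symbols[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Categorize vertices by their connections to driver and response genes
#'
#' Assigns one label per vertex: `D` (driver), `R` (response), `DIR`
#' (intermediate with a directed-respecting edge from a driver and an edge
#' into at least one response, i.e. on a length-2 driver-to-response path),
#' `DIIR` (on a simple directed-respecting path of length exactly 3 but on
#' no length-2 path), `DI` (adjacent from a driver only), `IR` (adjacent
#' into a response only), or `I` (neither). Driver and response labels take
#' precedence: a response gene that happens to sit on a length-2 path keeps
#' label `R`.
#'
#' A path step `j -> k` requires `a[k, j] = 1`; undirected ppi edges
#' satisfy both directions.
#'
#' @param network a `netpert_network`.
#' @return A tibble with columns `gene` and `category`.
#' @export
categorize <- function(network) {
  stopifnot(inherits(network, "netpert_network"))
  A <- network$activation
  n <- length(network$vertices)
  d_idx <- vertex_index(network, network$drivers)
  r_idx <- vertex_index(network, network$responses)

  # adjacency from drivers: k with a_kd = 1; adjacency into responses: a_rk = 1
  from_driver <- Matrix::rowSums(A[, d_idx, drop = FALSE]) > 0
  to_response <- Matrix::colSums(A[r_idx, , drop = FALSE]) > 0

  on3 <- on_length3_path(A, d_idx, r_idx)

  category <- rep("I", n)
  category[from_driver & !to_response] <- "DI"
  category[!from_driver & to_response] <- "IR"
  category[on3 & !(from_driver & to_response)] <- "DIIR"
  category[from_driver & to_response] <- "DIR"
  category[d_idx] <- "D"
  category[r_idx] <- "R"

  tibble::tibble(gene = network$vertices, category = category)
}

# vertices on a simple directed-respecting path of length exactly 3
# (driver -> k1 -> k2 -> response, all four vertices distinct)
on_length3_path <- function(A, d_idx, r_idx) {
  n <- nrow(A)
  on3 <- rep(FALSE, n)
  succ <- successor_list(A)
  r_set <- r_idx
  for (d in d_idx) {
    for (k1 in setdiff(succ[[d]], d)) {
      for (k2 in setdiff(succ[[k1]], c(d, k1))) {
        rs <- intersect(succ[[k2]], setdiff(r_set, c(d, k1, k2)))
        if (length(rs) > 0L) {
          on3[k1] <- TRUE
          on3[k2] <- TRUE
        }
      }
    }
  }
  on3
}

# successors of v (vertices k with an edge v -> k, i.e. a_kv = 1), by column
successor_list <- function(A) {
  At <- methods::as(A, "TsparseMatrix")
  split(At@i + 1L, factor(At@j + 1L, levels = seq_len(nrow(A))))
}

#' @method tidy netpert_network
#' @export
tidy.netpert_network <- function(x, ...) {
  At <- methods::as(x$activation, "TsparseMatrix")
  tibble::tibble(
    source = x$vertices[At@j + 1L],
    target = x$vertices[At@i + 1L]
  ) |> dplyr::arrange(.data$source, .data$target)
}

#' @method glance netpert_network
#' @export
glance.netpert_network <- function(x, ...) {
  tibble::tibble(
    n_vertices = length(x$vertices),
    n_activation = Matrix::nnzero(x$activation),
    n_drivers = length(x$drivers),
    n_responses = length(x$responses),
    n_dropped_responses = length(x$dropped_responses)
  )
}
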