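#' Run the ranking methods on a network
#'
#' Computes the requested rankings at a common response time and joins
#' them into one table, one row per network vertex. The response time
#' defaults to the relaxation time `tau_r` at which a fraction `r` of
#' the driver density has escaped; `r = 0` is rejected because it
#' formally gives zero weight to every gene. Identical inputs and
#' configuration produce identical output.
#'
#' @param network a `netpert_network`.
#' @param r escaped-density fraction in `(0, 1)` setting the response
#'   time (default 0.5).
#' @param n_t convolution intervals for the perturbation weights
#'   (default 2).
#' @param methods subset of `"netpert"`, `"netpert_endpoints"`, `"bc"`,
#'   `"tiedie"`, `"short_time"`, `"log_fc"`.
#' @param t response time override; when given, `r` is ignored.
#' @param response_log_fc optional tibble `gene`, `log_fc` for the
#'   `log_fc` benchmark.
#' @return A `netpert_ranking` tibble with columns `gene`, `category`,
#'   then `<method>_score` / `<method>_rank` pairs, ordered by the first
#'   method's rank then symbol. Attributes record the configuration
#'   (`r`, `t`, `n_t`, `tau`, `realized_escape`, `methods`).
#' @examples
#' net <- make_motif("parallel2")
#' netpert_run(net, methods = c("netpert", "bc"))
#' @export
netpert_run <- function(network,
                        r = 0.5, n_t = 2,
                        methods = c("netpert", "bc", "tiedie"),
                        t = NULL,
                        response_log_fc = NULL) {
  stopifnot(inherits(network, "netpert_network"))
  allowed <- c("netpert", "netpert_endpoints", "bc", "tiedie",
               "short_time", "log_fc")
  methods <- match.arg(methods, allowed, several.ok = TRUE)
  t_given <- !is.null(t)
  if (is.null(t)) {
    if (r <= 0 || r >= 1) {
      stop("r must be in (0, 1): r = 0 formally gives zero values for all genes")
    }
    tau_tbl <- relaxation_time(network, r)
    t <- tau_tbl$tau
  }
  realized <- escaped_density(network, t)

  out <- categorize(network)
  for (m in methods) {
    cols <- switch(
      m,
      netpert = {
        w <- netpert_weights(network, t = t, n_t = n_t)
        stats::setNames(
          w[c("gene", "weight", "rank")],
          c("gene", "netpert_score", "netpert_rank"))
      },
      netpert_endpoints = {
        w <- netpert_weights(network, t = t, n_t = n_t,
                             include_endpoints = TRUE)
        stats::setNames(
          w[c("gene", "weight", "rank")],
          c("gene", "netpert_endpoints_score", "netpert_endpoints_rank"))
      },
      bc = {
        b <- betweenness_subset(network)
        stats::setNames(b[c("gene", "bc_score", "rank")],
                        c("gene", "bc_score", "bc_rank"))
      },
      tiedie = {
        z <- tiedie_scores(network, t = t)
        stats::setNames(z[c("gene", "linking", "rank")],
                        c("gene", "tiedie_score", "tiedie_rank"))
      },
      short_time = {
        s <- short_time_weights(network)
        stats::setNames(s[c("gene", "path2_count", "rank")],
                        c("gene", "short_time_score", "short_time_rank"))
      },
      log_fc = {
        if (is.null(response_log_fc)) {
          stop("method 'log_fc' needs `response_log_fc` (gene, log_fc)")
        }
        lf <- rank_by_log_fc(response_log_fc)
        stats::setNames(lf[c("gene", "log_fc", "rank")],
                        c("gene", "log_fc_score", "log_fc_rank"))
      }
    )
    out <- dplyr::left_join(out, cols, by = "gene")
  }
  first_rank <- paste0(methods[1], "_rank")
  out <- dplyr::arrange(out, .data[[first_rank]], .data$gene)
  structure(out,
            class = c("netpert_ranking", class(out)),
            r = if (t_given) NA_real_ else r,
            t = t, n_t = n_t, tau = t,
            realized_escape = realized,
            methods = methods)
}

#' @method glance netpert_ranking
#' @export
glance.netpert_ranking <- function(x, ...) {
  tibble::tibble(
    n_vertices = nrow(x),
    t = attr(x, "t"),
    n_t = attr(x, "n_t"),
    realized_escape = attr(x, "realized_escape"),
    methods = paste(attr(x, "methods"), collapse = ",")
  )
}

#' Write a ranking table with configuration header
#'
#' @param ranking a `netpert_ranking`.
#' @param path output TSV path.
#' @param seed optional seed to record in the header.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path, seed = NULL) {
  stopifnot(inherits(ranking, "netpert_ranking"))
  comments <- c(
    paste0("netpertr ", as.character(utils::packageVersion("netpertr"))),
    paste0("t = ", format(attr(ranking, "t"), digits = 12),
           "; n_t = ", attr(ranking, "n_t"),
           "; realized escaped density = ",
           format(attr(ranking, "realized_escape"), digits = 12)),
    paste0("methods = ", paste(attr(ranking, "methods"), collapse = ","))
  )
  if (!is.null(seed)) comments <- c(comments, paste0("seed = ", seed))
  write_tsv_commented(ranking, path, comments = comments)
}

#' Evaluate a ranking table against a compound assay table
#'
#' Wrapper chaining [compound_to_target_scores()] and
#' [evaluate_groups()]: collapses the assay records to per-target
#' most-potent scores, then correlates every `*_rank` column of the
#' ranking with those scores within each gene group.
#'
#' @param ranking a `netpert_ranking` (or any data frame with `gene`,
#'   `category` and `*_rank` columns).
#' @param assay assay records (`compound`, `targets`, `score`).
#' @param max_targets compound target-count cutoff (default 5).
#' @param p_method passed to [spearman_cor()].
#' @return The group report tibble from [evaluate_groups()].
#' @export
netpert_evaluate <- function(ranking, assay, max_targets = 5, p_method = "t") {
  target_scores <- compound_to_target_scores(assay, max_targets = max_targets)
  evaluate_groups(ranking, target_scores, p_method = p_method)
}
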