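#' Collapse compound assay records to per-target inhibition scores
#'
#' Assay scores are percentages of vehicle control: 0 means complete
#' inhibition, 100 no effect, so the most potent score for a target is
#' the numerically smallest. Compounds listing more than `max_targets`
#' targets are excluded entirely (their activity cannot be attributed),
#' and each remaining target is assigned the most potent score among the
#' compounds that list it.
#'
#' @param records data frame with columns `compound`, `targets` (either
#'   a list-column of character vectors or `;`-separated strings) and
#'   `score`.
#' @param max_targets maximum number of listed targets for a compound to
#'   be retained (default 5).
#' @return A tibble with columns `target`, `score` (most potent),
#'   `best_compound` and `n_compounds`; attribute `compound_map` holds
#'   the retained long compound-target table used to count tested drugs.
#' @examples
#' records <- tibble::tibble(
#'   compound = c("drugA", "drugB"),
#'   targets = c("STAT3;JAK2", "STAT3"),
#'   score = c(40, 73)
#' )
#' compound_to_target_scores(records)
#' @export
compound_to_target_scores <- function(records, max_targets = 5) {
  stopifnot(is.data.frame(records))
  required <- c("compound", "targets", "score")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("`records` is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- tibble::as_tibble(records)
  if (!is.list(records$targets)) {
    records$targets <- strsplit(as.character(records$targets), ";", fixed = TRUE)
  }
  records$targets <- lapply(records$targets, function(x) unique(trimws(x[x != ""])))
  if (any(records$score < 0, na.rm = TRUE)) stop("assay scores must be nonnegative")

  retained <- records[lengths(records$targets) >= 1L &
                        lengths(records$targets) <= max_targets, ]
  long <- tidyr::unnest(retained, "targets") |>
    dplyr::rename(target = "targets")
  if (nrow(long) == 0L) {
    warning("no compounds retained after the max_targets filter")
    out <- tibble::tibble(target = character(), score = numeric(),
                          best_compound = character(), n_compounds = integer())
    attr(out, "compound_map") <- long
    return(out)
  }
  out <- long |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(
      best_compound = .data$compound[which.min(.data$score)],
      n_compounds = dplyr::n(),
      score = min(.data$score),
      .groups = "drop"
    ) |>
    dplyr::select("target", "score", "best_compound", "n_compounds") |>
    dplyr::arrange(.data$target)
  attr(out, "compound_map") <- dplyr::select(long, "compound", "target", "score")
  out
}

#' Spearman rank correlation with a two-sided p-value
#'
#' Computes rho on average ranks (ties allowed). The two-sided p-value
#' uses the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` with
#' `n - 2` degrees of freedom, or an exact permutation distribution of
#' rho for small samples when `p_method = "permutation"`.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`.
#' @param p_method `"t"` (default) or `"permutation"` (exact, requires
#'   `n < 10`).
#' @return A one-row tibble with columns `rho`, `p_value`, `n`,
#'   `p_method`.
#' @export
spearman_cor <- function(x, y, p_method = c("t", "permutation")) {
  p_method <- match.arg(p_method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("Spearman rho is undefined for a constant input vector")
  }
  rho <- stats::cor(rx, ry)
  if (p_method == "t") {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  } else {
    if (n >= 10L) stop("exact permutation p-value supported for n < 10 only")
    perms <- all_permutations(n)
    null_rho <- apply(perms, 1L, function(pp) stats::cor(rx, ry[pp]))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  }
  tibble::tibble(rho = rho, p_value = p, n = n, p_method = p_method)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Correlate method rankings with assay scores by gene group
#'
#' For each ranking method and each gene group (driver plus response
#' genes; intermediates; the entire network), computes the Spearman
#' correlation between the method's rank and the per-target assay score
#' over the tested proteins in the group. Rank 1 is the method's top
#' prediction and score 0 is complete inhibition, so a positive rho
#' means higher-ranked targets show stronger inhibition. Groups with
#' fewer than 3 tested proteins are skipped with a message.
#'
#' @param ranking data frame with columns `gene`, `category`, and one or
#'   more `*_rank` columns (e.g. the output of [netpert_run()]).
#' @param target_scores per-target assay scores from
#'   [compound_to_target_scores()] (columns `target`, `score`).
#' @param methods rank columns to evaluate; default all `*_rank`
#'   columns.
#' @param p_method passed to [spearman_cor()].
#' @return A tibble with columns `group`, `method`, `n_proteins`,
#'   `n_drugs`, `rho`, `p_value`.
#' @export
evaluate_groups <- function(ranking, target_scores,
                            methods = NULL, p_method = "t") {
  stopifnot(is.data.frame(ranking), is.data.frame(target_scores))
  if (!all(c("gene", "category") %in% names(ranking))) {
    stop("`ranking` needs `gene` and `category` columns")
  }
  rank_cols <- grep("_rank$", names(ranking), value = TRUE)
  if (!is.null(methods)) {
    methods <- ifelse(grepl("_rank$", methods), methods, paste0(methods, "_rank"))
    missing_m <- setdiff(methods, rank_cols)
    if (length(missing_m) > 0L) {
      stop("rank column(s) not found: ", paste(missing_m, collapse = ", "))
    }
    rank_cols <- methods
  }
  if (length(rank_cols) == 0L) stop("`ranking` has no *_rank columns")

  tested <- dplyr::inner_join(
    tibble::as_tibble(ranking),
    dplyr::select(tibble::as_tibble(target_scores), "target", "score"),
    by = c(gene = "target")
  )
  if (nrow(tested) == 0L) {
    stop("no overlap between assay targets and network vertices")
  }
  compound_map <- attr(target_scores, "compound_map")

  groups <- list(
    driver_response = c("D", "R"),
    intermediates = c("DIR", "DIIR", "DI", "IR", "I"),
    entire_network = c("D", "R", "DIR", "DIIR", "DI", "IR", "I")
  )
  purrr::imap(groups, function(cats, group_name) {
    sub <- dplyr::filter(tested, .data$category %in% cats)
    if (nrow(sub) < 3L) {
      message("group '", group_name, "' has ", nrow(sub),
              " tested protein(s) (< 3), skipped")
      return(NULL)
    }
    n_drugs <- if (!is.null(compound_map)) {
      dplyr::n_distinct(compound_map$compound[compound_map$target %in% sub$gene])
    } else {
      NA_integer_
    }
    purrr::map(rank_cols, function(col) {
      ct <- tryCatch(
        spearman_cor(sub[[col]], sub$score, p_method = p_method),
        error = function(e) {
          message("group '", group_name, "', method '",
                  sub("_rank$", "", col), "': ", conditionMessage(e))
          tibble::tibble(rho = NA_real_, p_value = NA_real_)
        }
      )
      tibble::tibble(
        group = group_name,
        method = sub("_rank$", "", col),
        n_proteins = nrow(sub),
        n_drugs = n_drugs,
        rho = ct$rho,
        p_value = ct$p_value
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}

#' Rank response genes by log fold-change
#'
#' The benchmark prioritization that orders differentially expressed
#' response genes by decreasing log fold-change (up-regulated first),
#' with average ranks on ties. Genes with missing values are excluded
#' with a warning.
#'
#' @param response_table data frame with columns `gene` and `log_fc`.
#' @return A tibble with columns `gene`, `log_fc`, `rank`.
#' @export
rank_by_log_fc <- function(response_table) {
  stopifnot(is.data.frame(response_table))
  if (!all(c("gene", "log_fc") %in% names(response_table))) {
    stop("`response_table` needs `gene` and `log_fc` columns")
  }
  tbl <- tibble::as_tibble(response_table)
  missing_fc <- !is.finite(tbl$log_fc)
  if (any(missing_fc)) {
    warning(sum(missing_fc), " response gene(s) without log fold-change excluded")
    tbl <- tbl[!missing_fc, ]
  }
  if (nrow(tbl) == 0L) stop("no response genes with log fold-change values")
  tbl$rank <- rank_weights(tbl$log_fc)
  dplyr::arrange(dplyr::select(tbl, "gene", "log_fc", "rank"),
                 .data$rank, .data$gene)
}
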