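# Group comparisons: Kruskal-Wallis across land-use classes, Dunn
# two-by-two post-hoc z-tests with Holm (or Bonferroni) adjustment,
# and a compact letter display from the non-significance graph.

#' Kruskal-Wallis test with Dunn post-hoc letters
#'
#' Rank-based comparison of two or more groups (tie-corrected H,
#' chi-square approximation with df = groups - 1), followed by Dunn's
#' pairwise z-tests on the pooled mean ranks with multiplicity
#' adjustment, and a compact letter display in which two groups share a
#' letter exactly when they are not significantly different at `alpha`.
#' If every value in every group is identical the test is degenerate
#' and reported as H = 0, p = 1.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each with
#'   >= 1 value).
#' @param p_adjust `"holm"` (default) or `"bonferroni"`.
#' @param alpha significance level for the letter display.
#' @return Object of class `group_comparison`: list with `H`, `df`,
#'   `p_value`, `pairwise` (symmetric matrix of adjusted p-values),
#'   `letters` (named character), `mean_rank`, `n`.
#' @examples
#' kruskal_wallis(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)))
#' @export
kruskal_wallis <- function(groups, p_adjust = c("holm", "bonferroni"),
                           alpha = 0.05) {
  p_adjust <- match.arg(p_adjust)
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 1L))
    stop("every group needs at least 1 value")
  if (is.null(names(groups)))
    names(groups) <- sprintf("g%d", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  n <- table(g)
  k <- length(groups)

  rk <- rank(x)
  mean_rank <- tapply(rk, g, mean)

  if (length(unique(x)) == 1L) {            # fully degenerate data
    H <- 0; p <- 1
  } else {
    kt <- stats::kruskal.test(x, g)
    H <- unname(kt$statistic); p <- kt$p.value
  }

  # Dunn pairwise z on pooled mean ranks, tie-corrected variance
  N <- length(x)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pw <- matrix(NA_real_, k, k, dimnames = list(names(groups),
                                               names(groups)))
  pr <- c(); labs <- list()
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
               (1 / n[[i]] + 1 / n[[j]]))
    z <- if (se > 0) (mean_rank[[i]] - mean_rank[[j]]) / se else 0
    pr <- c(pr, 2 * stats::pnorm(-abs(z)))
    labs[[length(labs) + 1L]] <- c(i, j)
  }
  pr <- stats::p.adjust(pr, method = p_adjust)
  for (m in seq_along(labs)) {
    ij <- labs[[m]]
    pw[ij[1], ij[2]] <- pw[ij[2], ij[1]] <- pr[m]
  }
  diag(pw) <- 1

  structure(list(H = H, df = k - 1L, p_value = p, pairwise = pw,
                 letters = compact_letters(pw, alpha = alpha,
                                           order_by = -unlist(mean_rank)),
                 mean_rank = mean_rank, n = as.integer(n)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g\n",
              x$H, x$df, x$p_value))
  disp <- data.frame(n = x$n, mean_rank = round(unlist(x$mean_rank), 2),
                     letters = x$letters[names(x$mean_rank)])
  print(disp)
  invisible(x)
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Two groups share a letter exactly when their adjusted p-value is
#' above `alpha`. Letters correspond to the maximal cliques of the
#' non-significance graph, enumerated exactly (group counts here are
#' tiny), ordered by `order_by`.
#'
#' @param pairwise symmetric matrix of (adjusted) p-values with
#'   dimnames.
#' @param alpha significance threshold.
#' @param order_by numeric used to order the letters (default: row
#'   order).
#' @return Named character vector of letter strings.
#' @export
compact_letters <- function(pairwise, alpha = 0.05, order_by = NULL) {
  k <- nrow(pairwise)
  nm <- rownames(pairwise)
  adj <- pairwise > alpha
  diag(adj) <- FALSE
  # Bron-Kerbosch maximal cliques (k <= ~10 here)
  cliques <- list()
  bk <- function(R, P, X) {
    if (length(P) == 0L && length(X) == 0L) {
      cliques[[length(cliques) + 1L]] <<- R
      return()
    }
    for (v in P) {
      nb <- which(adj[v, ])
      bk(c(R, v), intersect(P, nb), intersect(X, nb))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(0), seq_len(k), integer(0))
  if (is.null(order_by)) order_by <- seq_len(k)
  first <- vapply(cliques, function(cl) min(rank(order_by)[cl]),
                  numeric(1))
  cliques <- cliques[order(first)]
  letters_out <- rep("", k)
  for (m in seq_along(cliques))
    letters_out[cliques[[m]]] <- paste0(letters_out[cliques[[m]]],
                                        letters[m])
  stats::setNames(letters_out, nm)
}
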