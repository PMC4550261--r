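# David's Score dominance ranking from agonistic interaction records.

#' Build an agonistic interaction matrix from a win/loss record
#'
#' @param interactions Tibble with `winner_id`, `loser_id` (one row per
#'   decided interaction).
#' @param ids Optional vector fixing the individuals and their order;
#'   defaults to everyone appearing in the record.
#' @return An N x N integer matrix with `s[i, j]` = wins of `i` over `j` and
#'   zero diagonal.
#' @export
interaction_matrix <- function(interactions, ids = NULL) {
  assert_columns(interactions, c("winner_id", "loser_id"), "interactions")
  ids <- ids %||% sort(unique(c(interactions$winner_id, interactions$loser_id)))
  if (length(ids) < 2) abort("need at least 2 individuals")
  m <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  tab <- table(factor(interactions$winner_id, levels = ids),
               factor(interactions$loser_id, levels = ids))
  m[] <- as.integer(tab)
  if (any(diag(m) != 0)) abort("an individual cannot defeat itself")
  m
}

#' Dyadic dominance indices
#'
#' For each ordered dyad the win proportion is `P_ij = s_ij / n_ij` with
#' `n_ij = s_ij + s_ji`. The default chance-corrected variant shrinks sparse
#' dyads toward 0.5: `D_ij = P_ij - (P_ij - 0.5) / (n_ij + 1)`. Dyads that
#' never interacted get `D_ij = 0.5`. `D_ij + D_ji = 1` always.
#'
#' @param mat Interaction matrix from [interaction_matrix()].
#' @param method `"corrected"` (default, chance-corrected) or `"raw"` (plain
#'   win proportions).
#' @return An N x N matrix of dyadic indices with 0 diagonal.
#' @export
dyadic_dominance <- function(mat, method = c("corrected", "raw")) {
  method <- match.arg(method)
  if (!is.matrix(mat) || nrow(mat) != ncol(mat) || nrow(mat) < 2) {
    abort("`mat` must be a square matrix with N >= 2")
  }
  if (any(mat < 0)) abort("interaction counts must be non-negative")
  n_ij <- mat + t(mat)
  p <- ifelse(n_ij > 0, mat / ifelse(n_ij > 0, n_ij, 1), 0.5)
  d <- if (method == "corrected") p - (p - 0.5) / (n_ij + 1) else p
  diag(d) <- 0
  d
}

#' David's Scores and Normalized David's Scores
#'
#' Computes, from the dyadic index matrix `D`: per-individual winning success
#' `w_i = sum_j D_ij`, its weighted second-order form
#' `w2_i = sum_j w_j D_ij`, the losing analogues `l_i = sum_j D_ji` and
#' `l2_i = sum_j l_j D_ji`, the David's Score `DS = w + w2 - l - l2`
#' (summing to zero over individuals), and the normalized score
#' `NDS = (DS + N(N-1)/2) / N` with mean `(N-1)/2`. Ordinal ranks (1 = top)
#' break NDS ties by total wins, then by id.
#'
#' @param mat Interaction matrix from [interaction_matrix()].
#' @param method Dyadic index variant, see [dyadic_dominance()].
#' @return A tibble: `id`, `DS`, `NDS`, `rank`, `total_wins`.
#' @export
davids_score <- function(mat, method = c("corrected", "raw")) {
  method <- match.arg(method)
  d <- dyadic_dominance(mat, method)
  n <- nrow(d)
  w <- rowSums(d)
  w2 <- as.numeric(d %*% w)
  l <- colSums(d)
  l2 <- as.numeric(t(d) %*% l)
  ds <- w + w2 - l - l2
  nds <- (ds + n * (n - 1) / 2) / n
  ids <- rownames(mat) %||% as.character(seq_len(n))
  out <- tibble::tibble(
    id = ids, DS = unname(ds), NDS = unname(nds),
    total_wins = unname(rowSums(mat))
  )
  ord <- order(-out$NDS, -out$total_wins, out$id)
  out$rank <- integer(n)
  out$rank[ord] <- seq_len(n)
  dplyr::select(out, "id", "DS", "NDS", "rank", "total_wins")
}

#' Rank females and report the rank-age collinearity diagnostic
#'
#' Convenience wrapper: builds the interaction matrix, computes Normalized
#' David's Scores and, when ages are supplied, the Spearman rank correlation
#' between dominance rank and age. In small matrilineal groups rank and age can
#' be perfectly correlated, in which case rank cannot enter a model alongside
#' age; the diagnostic makes that visible.
#'
#' @param interactions Win/loss record (see [interaction_matrix()]).
#' @param roster Optional tibble `female_id`, `age`.
#' @param method Dyadic index variant.
#' @return A tibble as [davids_score()], plus `age` and an attribute
#'   `rank_age_cor` when ages are available.
#' @export
rank_females <- function(interactions, roster = NULL,
                         method = c("corrected", "raw")) {
  ids <- if (!is.null(roster)) roster$female_id else NULL
  scores <- davids_score(interaction_matrix(interactions, ids), method)
  if (!is.null(roster)) {
    assert_columns(roster, c("female_id", "age"), "roster")
    scores <- dplyr::left_join(scores,
                               dplyr::select(roster, id = "female_id", "age"),
                               by = "id")
    attr(scores, "rank_age_cor") <- cor(-scores$rank, scores$age,
                                        method = "spearman")
  }
  scores
}
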