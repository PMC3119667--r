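#' Maximum-weight assignment by the Hungarian algorithm
#'
#' Solves the square assignment problem exactly in O(n^3) time using the
#' shortest-augmenting-path formulation with dual potentials (weights are
#' complemented internally, so maximization is performed). Ties are resolved
#' deterministically by preferring the lowest column index.
#'
#' @param weights Square numeric matrix of finite weights; entry `[i, j]`
#'   is the gain of assigning row `i` to column `j`.
#' @return A list with `assignment` (integer vector, `assignment[i]` = column
#'   given to row `i`, a permutation) and `weight` (the maximal total weight).
#' @examples
#' hungarian_max(rbind(c(1, 2), c(3, 4)))$assignment  # 2 1
#' @export
hungarian_max <- function(weights) {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights))
    stop("weights must be a square matrix")
  if (length(weights) && !all(is.finite(weights))) stop("weights must be finite")
  n <- nrow(weights)
  if (n == 0L) return(list(assignment = integer(0L), weight = 0))
  cost <- max(weights) - weights        # minimize the complementary cost
  # columns are 0..n with 0 a virtual start column; stored at index j+1
  u <- numeric(n)                       # row potentials
  v <- numeric(n + 1L)                  # column potentials
  p <- integer(n + 1L)                  # p[j+1] = row matched to column j
  way <- integer(n)                     # way[j] = predecessor column of j
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- logical(n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])
      cur <- cost[i0, free] - u[i0] - v[free + 1L]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      j1 <- free[which.min(minv[free])]   # lowest index wins ties
      delta <- minv[j1]
      sel <- which(used)                  # shifted column indices
      rows <- p[sel]
      u[rows[rows > 0L]] <- u[rows[rows > 0L]] + delta
      v[sel] <- v[sel] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {                              # augment along the alternating path
      j1 <- way[j0]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  assignment[p[-1L]] <- seq_len(n)
  list(assignment = assignment,
       weight = sum(weights[cbind(seq_len(n), assignment)]))
}
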