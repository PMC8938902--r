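## Task definitions and balanced block sequences.

#' Canonical condition sets
#'
#' Returns the condition set of one of the three tasks. The whole-body task
#' crosses three body parts (feet, hand, lips) with two actions (squeeze,
#' push), giving six conditions; the face task has four subparts in cortical
#' order forehead < nose < lips < tongue; the finger task has the five digits
#' D1..D5 of one hand.
#'
#' @param taskId `"body"`, `"face"`, or `"finger"`.
#' @return a [ConditionSet-class].
#' @examples
#' makeTask("body")
#' @export
makeTask <- function(taskId) {
  if (!is.character(taskId) || length(taskId) != 1L ||
      !taskId %in% c("body", "face", "finger"))
    stop("unknown taskId: must be one of 'body', 'face', 'finger'",
         call. = FALSE)
  switch(taskId,
    body = {
      parts <- c("feet", "hand", "lips")
      actions <- c("squeeze", "push")
      grid <- expand.grid(action = actions, part = parts,
                          stringsAsFactors = FALSE)[, 2:1]
      conds <- paste(grid$part, grid$action, sep = ".")
      new("ConditionSet", taskId = "body", conditions = conds,
          subpartOrder = parts,
          actionFactor = data.frame(condition = conds, part = grid$part,
                                    action = grid$action,
                                    stringsAsFactors = FALSE))
    },
    face = new("ConditionSet", taskId = "face",
               conditions = c("forehead", "nose", "lips", "tongue"),
               subpartOrder = c("forehead", "nose", "lips", "tongue"),
               actionFactor = data.frame()),
    finger = new("ConditionSet", taskId = "finger",
                 conditions = paste0("D", 1:5),
                 subpartOrder = paste0("D", 1:5),
                 actionFactor = data.frame()))
}

#' Localizer condition set (toes, hand, lips vs all others)
#'
#' The independent movement localizer used to define selectivity-based ROIs:
#' one condition per primary body part, with movement blocks interleaved with
#' rest.
#'
#' @return a [ConditionSet-class] with taskId `"localizer"`.
#' @export
makeLocalizer <- function() {
  new("ConditionSet", taskId = "localizer",
      conditions = c("feet", "hand", "lips"),
      subpartOrder = c("feet", "hand", "lips"),
      actionFactor = data.frame())
}

#' Default session recipes
#'
#' Study-style block timing: 8 s movement blocks repeated 4 times per
#' condition per run with 5 rest blocks and TR 1.45 s for the body (4 runs)
#' and face (3 runs) tasks; 9 s blocks and 4 runs for the finger task; 12 s
#' blocks interleaved with as many 12 s rest blocks, one run, for the
#' localizer. High-pass cutoffs are 150, 119, 150 and 280 s respectively.
#' Volumes per run are computed from the block schedule plus a 12-volume
#' haemodynamic tail.
#'
#' @param taskId `"body"`, `"face"`, `"finger"`, or `"localizer"`.
#' @return a [SessionRecipe-class].
#' @export
defaultRecipe <- function(taskId) {
  p_ <- switch(taskId,
    body      = list(k = 6L, blockS = 8,  b = 4L, rest = 5L,  runs = 4L, hp = 150),
    face      = list(k = 4L, blockS = 8,  b = 4L, rest = 5L,  runs = 3L, hp = 119),
    finger    = list(k = 5L, blockS = 9,  b = 4L, rest = 5L,  runs = 4L, hp = 150),
    localizer = list(k = 3L, blockS = 12, b = 4L, rest = 12L, runs = 1L, hp = 280),
    stop("unknown taskId: ", taskId, call. = FALSE))
  tr <- 1.45
  nSlots <- p_$k * p_$b + p_$rest
  nVol <- as.integer(ceiling(nSlots * p_$blockS / tr)) + 12L
  new("SessionRecipe", trS = tr, blockS = p_$blockS,
      blocksPerConditionPerRun = p_$b, restBlocksPerRun = p_$rest,
      nRuns = p_$runs, nVolumesPerRun = nVol, hpCutoffS = p_$hp)
}

#' First-order counterbalanced block sequences
#'
#' Generates one block sequence per run such that each condition appears
#' exactly `blocksPerConditionPerRun` times per run and, across the whole
#' session, the counts of ordered transitions c_i -> c_j (i != j, within
#' runs) differ by at most 1 -- i.e. each condition is (as nearly as possible)
#' equally preceded by every other condition. The sequence is found by a
#' seeded greedy search that always extends with a condition minimising the
#' current transition count, restarting until exact balance is achieved.
#'
#' @param conditionSet a [ConditionSet-class].
#' @param recipe a [SessionRecipe-class].
#' @param seed integer seed; the result is deterministic given the seed.
#' @param maxRestarts greedy restarts before giving up (then the best
#'   sequence found is returned with a warning).
#' @return list of character vectors, one per run.
#' @export
balancedSequence <- function(conditionSet, recipe, seed, maxRestarts = 400L) {
  conds <- conditionSet@conditions
  k <- length(conds)
  b <- recipe@blocksPerConditionPerRun
  M <- recipe@nRuns
  if (b < 1L) stop("blocksPerConditionPerRun must be >= 1", call. = FALSE)
  if (k == 1L) {
    warning("single condition: transition balance is infeasible, ",
            "falling back to simple repetition")
    return(replicate(M, rep(conds, b), simplify = FALSE))
  }
  rng <- localRNG(seed)
  best <- NULL
  bestSpread <- Inf
  for (attempt in seq_len(maxRestarts)) {
    trans <- matrix(0L, k, k)
    runs <- vector("list", M)
    for (m in seq_len(M)) {
      remaining <- rep(b, k)
      seqr <- integer(k * b)
      prev <- 0L
      for (pos in seq_along(seqr)) {
        cand <- which(remaining > 0L)
        if (prev > 0L && length(cand) > 1L) cand <- setdiff(cand, prev)
        score <- if (prev > 0L) trans[prev, cand] else rep(0L, length(cand))
        cand <- cand[score == min(score)]
        ## among balance-equivalent candidates, spend the most-remaining
        ## condition first so the run cannot end in a forced repeat
        cand <- cand[remaining[cand] == max(remaining[cand])]
        pick <- if (length(cand) == 1L) cand else cand[rng$int(length(cand))]
        seqr[pos] <- pick
        if (prev > 0L) trans[prev, pick] <- trans[prev, pick] + 1L
        remaining[pick] <- remaining[pick] - 1L
        prev <- pick
      }
      runs[[m]] <- conds[seqr]
    }
    off <- trans[row(trans) != col(trans)]
    spread <- max(off) - min(off) + 100L * sum(diag(trans) > 0L)
    if (spread < bestSpread) {
      bestSpread <- spread
      best <- runs
    }
    if (spread <= 1L) return(best)
  }
  warning(sprintf(paste0("transition balance max-min = %d not reduced to 1 ",
                         "after %d restarts; returning best sequence"),
                  bestSpread, maxRestarts))
  best
}

#' Count ordered condition transitions across a session
#'
#' Tallies within-run first-order transitions c_i -> c_j over a list of run
#' sequences. Used to verify counterbalancing.
#'
#' @param runSequences list of character vectors.
#' @param conditions condition labels fixing the matrix order.
#' @return integer condition x condition matrix of transition counts.
#' @export
transitionCounts <- function(runSequences, conditions) {
  k <- length(conditions)
  trans <- matrix(0L, k, k, dimnames = list(conditions, conditions))
  for (s in runSequences) {
    idx <- match(s, conditions)
    if (anyNA(idx)) stop("sequence contains unknown condition labels")
    if (length(idx) > 1L)
      for (i in seq_len(length(idx) - 1L))
        trans[idx[i], idx[i + 1L]] <- trans[idx[i], idx[i + 1L]] + 1L
  }
  trans
}

#' Lay out movement and rest blocks on the run timeline
#'
#' Assigns the movement blocks of `sequence` and the recipe's rest blocks to
#' contiguous equal-duration slots, with rest slots spread evenly through the
#' run (when rest and movement counts are equal this reduces to strict
#' interleaving, as in the localizer). Returns onsets/durations of the
#' movement blocks only; rest is implicit baseline.
#'
#' @param sequence character vector of movement block labels.
#' @param recipe a [SessionRecipe-class].
#' @return data.frame with columns `condition`, `onsetS`, `durationS`.
#' @export
scheduleBlocks <- function(sequence, recipe) {
  nb <- length(sequence)
  nr <- recipe@restBlocksPerRun
  total <- nb + nr
  restPos <- if (nr > 0L)
    round(seq_len(nr) * (total + 1) / (nr + 1)) else integer()
  ## guard against rounding collisions for extreme rest fractions
  restPos <- unique(pmin(pmax(restPos, 1L), total))
  while (length(restPos) < nr) {
    free <- setdiff(seq_len(total), restPos)
    restPos <- sort(c(restPos, free[1L]))
  }
  movSlots <- setdiff(seq_len(total), restPos)
  onsets <- (movSlots - 1L) * recipe@blockS
  data.frame(condition = sequence, onsetS = onsets,
             durationS = rep(recipe@blockS, nb), stringsAsFactors = FALSE)
}
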