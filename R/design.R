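#' Factor levels of the crowding design
#'
#' Canonical orderings used everywhere in the package, including the dummy
#' coding of the regression model: designs `blocked < precued < random`,
#' locations `up < down < left < right`, flanker conditions
#' `none < inward < outward`.
#'
#' @name design_levels
#' @keywords internal
NULL

design_levels <- c("blocked", "precued", "random")
location_levels <- c("up", "down", "left", "right")
flanker_levels <- c("none", "inward", "outward")

as_design <- function(x) factor(x, levels = design_levels)
as_location <- function(x) factor(x, levels = location_levels)
as_flanker <- function(x) factor(x, levels = flanker_levels)

check_levels <- function(x, levels, what) {
  bad <- setdiff(unique(as.character(x)), levels)
  if (length(bad) > 0) {
    abort(sprintf("unknown %s level(s): %s", what, paste(bad, collapse = ", ")))
  }
  invisible(x)
}

#' Enumerate the 36 condition cells
#'
#' One cell per combination of design (blocked, precued, random), target
#' location (up, down, left, right) and flanker condition (none, inward,
#' outward). The order is design-major, then location, then flanker, and is
#' the reference ordering for every tabular output of the package.
#'
#' @return A tibble with 36 rows and columns `design`, `location`, `flanker`
#'   (factors with the canonical level orders) and `cell`, a stable string key
#'   of the form `"design/location/flanker"`.
#' @examples
#' condition_cells()
#' @export
condition_cells <- function() {
  grid <- expand.grid(
    flanker = flanker_levels,
    location = location_levels,
    design = design_levels,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  tibble::tibble(
    design = as_design(grid$design),
    location = as_location(grid$location),
    flanker = as_flanker(grid$flanker),
    cell = cell_key(grid$design, grid$location, grid$flanker)
  )
}

#' Stable string key for a condition cell
#'
#' @param design,location,flanker Vectors of factor levels (recycled).
#' @return Character vector `"design/location/flanker"`.
#' @examples
#' cell_key("blocked", "up", "outward")
#' @export
cell_key <- function(design, location, flanker) {
  check_levels(design, design_levels, "design")
  check_levels(location, location_levels, "location")
  check_levels(flanker, flanker_levels, "flanker")
  paste(as.character(design), as.character(location), as.character(flanker),
        sep = "/")
}

#' Study design parameters
#'
#' Container for the structural constants of the experiment. Defaults match
#' the reference cohort: 38 participants, 8 blocks of 120 trials per design
#' condition (2880 trials in all), thresholds per cell estimated from two
#' 40-trial staircase runs, targets at 7.5 degrees eccentricity,
#' centre-to-centre flanker spacing fixed at 1.1 times the letter size, and
#' letter sizes constrained to 0.1--3 degrees.
#'
#' The block arithmetic must close: `blocks_per_design * trials_per_block * 3`
#' designs must equal `runs_per_cell * trials_per_run * 36` cells (both 2880
#' under the defaults).
#'
#' @param n_participants Number of observers in the cohort.
#' @param blocks_per_design Blocks per design condition.
#' @param trials_per_block Trials in each block.
#' @param runs_per_cell Independent staircase runs per condition cell.
#' @param trials_per_run Trials per staircase run.
#' @param eccentricity_deg Target eccentricity, degrees of visual angle.
#' @param spacing_factor Flanker centre-to-centre spacing as a multiple of
#'   letter size; must exceed 1 so letters never overlap.
#' @param size_min_deg,size_max_deg Letter-size bounds, degrees.
#' @param sessions,blocks_per_session Session structure; metadata only, with
#'   no computational role.
#' @return An object of class `study_design` (a validated list).
#' @examples
#' study_design()
#' @export
study_design <- function(n_participants = 38,
                         blocks_per_design = 8,
                         trials_per_block = 120,
                         runs_per_cell = 2,
                         trials_per_run = 40,
                         eccentricity_deg = 7.5,
                         spacing_factor = 1.1,
                         size_min_deg = 0.1,
                         size_max_deg = 3.0,
                         sessions = 4,
                         blocks_per_session = 6) {
  d <- structure(
    list(
      n_participants = as.integer(n_participants),
      blocks_per_design = as.integer(blocks_per_design),
      trials_per_block = as.integer(trials_per_block),
      runs_per_cell = as.integer(runs_per_cell),
      trials_per_run = as.integer(trials_per_run),
      eccentricity_deg = eccentricity_deg,
      spacing_factor = spacing_factor,
      size_min_deg = size_min_deg,
      size_max_deg = size_max_deg,
      sessions = as.integer(sessions),
      blocks_per_session = as.integer(blocks_per_session)
    ),
    class = "study_design"
  )
  validate_study_design(d)
}

validate_study_design <- function(d) {
  n_cells <- nrow(condition_cells())
  lhs <- d$blocks_per_design * d$trials_per_block * length(design_levels)
  rhs <- d$runs_per_cell * d$trials_per_run * n_cells
  if (lhs != rhs) {
    abort(sprintf(
      "inconsistent design: %d blocks x %d trials x 3 designs = %d, but %d runs x %d trials x %d cells = %d",
      d$blocks_per_design, d$trials_per_block, lhs,
      d$runs_per_cell, d$trials_per_run, n_cells, rhs
    ))
  }
  if (d$size_min_deg >= d$size_max_deg) abort("size_min_deg must be < size_max_deg")
  if (d$spacing_factor <= 1) abort("spacing_factor must be > 1")
  if (d$n_participants < 1) abort("need at least one participant")
  d
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design>\n")
  cat(sprintf("  %d participants; %d blocks x %d trials per design (%d trials total)\n",
              x$n_participants, x$blocks_per_design, x$trials_per_block,
              x$blocks_per_design * x$trials_per_block * 3))
  cat(sprintf("  %d runs x %d trials per cell; sizes %.2g-%.2g deg at %.1f deg eccentricity\n",
              x$runs_per_cell, x$trials_per_run, x$size_min_deg, x$size_max_deg,
              x$eccentricity_deg))
  invisible(x)
}

#' Build one participant's trial schedule
#'
#' Lays out every trial slot for a single participant: per design condition,
#' `blocks_per_design` blocks of `trials_per_block` trials. In the blocked
#' design each block uses a single target location (each location gets
#' `blocks_per_design / 4` blocks) with the three flanker conditions equally
#' represented and randomly interleaved; in the precued and random designs
#' each block balances all 12 location x flanker combinations and shuffles
#' them. Block order within a design and trial order within a block are
#' randomised by `seed`; per-cell totals never change. For each cell, the
#' first half of its slots in chronological order form run 1 and the second
#' half run 2, matching how the staircase consumes them.
#'
#' Sizes are left unfilled (`NA`); the staircase assigns them at simulation
#' time.
#'
#' @param design A [study_design()]. `blocks_per_design` must be divisible by
#'   4 (blocked design) and `trials_per_block` by 3 and 12.
#' @param participant Participant identifier (scalar).
#' @param seed Integer seed controlling the interleaving.
#' @return A tibble with `design$blocks_per_design * design$trials_per_block *
#'   3` rows and columns `participant, design, location, flanker, cell,
#'   session, block, trial_in_block, run, trial, size_deg, correct`.
#' @examples
#' sched <- build_schedule(study_design(), participant = 1, seed = 1)
#' nrow(sched) # 2880
#' dplyr::count(sched, design, location, flanker) # 80 each
#' @export
build_schedule <- function(design = study_design(), participant = 1L, seed = 1L) {
  validate_study_design(design)
  n_loc <- length(location_levels)
  if (design$blocks_per_design %% n_loc != 0) {
    abort("blocks_per_design must be a multiple of 4 to balance locations in the blocked design")
  }
  if (design$trials_per_block %% (3 * n_loc) != 0) {
    abort("trials_per_block must be a multiple of 12 to balance location x flanker within blocks")
  }
  withr::local_seed(as.integer(seed))

  one_block <- function(des, block_idx) {
    if (des == "blocked") {
      loc <- location_levels[(block_idx - 1L) %% n_loc + 1L]
      slots <- expand.grid(
        location = loc,
        flanker = flanker_levels,
        rep = seq_len(design$trials_per_block / 3),
        stringsAsFactors = FALSE
      )
    } else {
      slots <- expand.grid(
        location = location_levels,
        flanker = flanker_levels,
        rep = seq_len(design$trials_per_block / 12),
        stringsAsFactors = FALSE
      )
    }
    slots <- slots[sample.int(nrow(slots)), c("location", "flanker")]
    slots$trial_in_block <- seq_len(nrow(slots))
    slots
  }

  per_design <- lapply(design_levels, function(des) {
    block_order <- sample.int(design$blocks_per_design)
    blocks <- lapply(seq_len(design$blocks_per_design), function(i) {
      b <- one_block(des, block_order[i])
      b$block <- i
      b
    })
    out <- do.call(rbind, blocks)
    out$design <- des
    out
  })
  sched <- do.call(rbind, per_design)

  # design blocks are themselves interleaved across sessions; record a session
  # index but keep design-major row order (computation is per cell anyway)
  blocks_total <- design$blocks_per_design * 3
  sched <- tibble::tibble(
    participant = participant,
    design = as_design(sched$design),
    location = as_location(sched$location),
    flanker = as_flanker(sched$flanker),
    cell = cell_key(sched$design, sched$location, sched$flanker),
    block = sched$block,
    trial_in_block = sched$trial_in_block
  )
  sched$session <- ((match(as.character(sched$design), design_levels) - 1L) *
                      design$blocks_per_design + sched$block - 1L) %/%
    (blocks_total %/% design$sessions) + 1L

  tpr <- design$trials_per_run
  sched <- dplyr::group_by(sched, .data$cell) |>
    dplyr::mutate(
      slot = dplyr::row_number(),
      run = (.data$slot - 1L) %/% tpr + 1L,
      trial = (.data$slot - 1L) %% tpr + 1L
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"slot")
  sched$size_deg <- NA_real_
  sched$correct <- NA
  sched[, c("participant", "design", "location", "flanker", "cell", "session",
            "block", "trial_in_block", "run", "trial", "size_deg", "correct")]
}
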