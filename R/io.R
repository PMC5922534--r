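# Reading and writing games, strategies and curves; fixture generation.

#' Read and write decision games as JSON
#'
#' The game file is a JSON object
#' `{"goal": number, "mode": "approaching"|"growing", "tau": number,
#' "options": [{"u": number, "p": number, "label": string}, ...]}` with
#' monetary utilities; stage-unit conversion happens on read, so a
#' round-trip reproduces the game exactly.
#'
#' @param game A [decision_game()].
#' @param path File path.
#' @param overshoot Optional override of the stored overshoot policy on
#'   read.
#' @return `read_game_json()` returns a `decision_game`;
#'   `write_game_json()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_game_json(standard_game(3), f)
#' read_game_json(f)$goal_stages
#' @export
write_game_json <- function(game, path) {
  stopifnot(inherits(game, "decision_game"))
  obj <- list(
    goal = game$monetary_goal,
    mode = game$mode,
    tau = game$tau,
    overshoot = game$overshoot,
    standard = game$standard,
    options = lapply(seq_len(nrow(game$options)), function(i) {
      list(
        u = game$options$monetary_u[i],
        p = game$options$p[i],
        label = game$options$label[i]
      )
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_game_json
#' @export
read_game_json <- function(path, overshoot = NULL) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  for (f in c("goal", "mode", "options")) {
    if (is.null(obj[[f]])) abort(paste0("Game file missing field `", f, "`."))
  }
  if (isTRUE(obj$standard)) {
    game <- standard_game(obj$goal)
    game$tau <- obj$tau %||% 1
    return(game)
  }
  decision_game(
    as_tibble(obj$options),
    goal = obj$goal, mode = obj$mode,
    tau = obj$tau %||% 1,
    overshoot = overshoot %||% obj$overshoot %||% "clamp"
  )
}

#' Read a payoff table from CSV
#'
#' Three columns `label,u,p` (monetary utility, win probability); the goal
#' and mode are supplied separately, e.g. as CLI flags.
#'
#' @param path CSV file path.
#' @return A tibble with columns `label`, `u`, `p`.
#' @export
read_payoff_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "u", "p") %in% names(df))) {
    abort("Payoff CSV needs columns `label`, `u`, `p`.")
  }
  as_tibble(df)
}

#' Read a strategy specification from JSON
#'
#' Either `{"name": "risky"}` / `{"name": "fix", "fix_utility": 6}` for a
#' named strategy, or `{"custom": {"2": {"1": 0.5, "2": 0.5}, ...}}`
#' mapping stage index to per-utility weights.
#'
#' @param path JSON file path.
#' @param game The [decision_game()] the strategy applies to.
#' @return A `decision_strategy`.
#' @export
read_strategy_json <- function(path, game) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(obj$custom)) {
    return(custom_strategy(game, obj$custom))
  }
  if (is.null(obj$name)) {
    abort("Strategy file needs either `name` or `custom`.")
  }
  named_strategy(game, obj$name, fix_utility = obj$fix_utility)
}

#' Write goal-reaching curves to CSV
#'
#' Columns `t`, `cdf`, `pmf`, `real_time`; metadata (game signature,
#' strategy, tau) as leading `#` comment lines.
#'
#' @param curve A `goal_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(curve, path) {
  stopifnot(inherits(curve, "goal_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# game: ", attr(curve, "signature")),
    paste0("# strategy: ", attr(curve, "strategy")),
    paste0("# tau: ", attr(curve, "tau"), " (real_time = t * tau)")
  ), con)
  utils::write.csv(
    as.data.frame(curve)[, c("t", "cdf", "pmf", "real_time")],
    con,
    row.names = FALSE
  )
  invisible(path)
}

#' Generate the worked example input files
#'
#' Writes ready-made game files: `standard` (standard games with goals 10,
#' 50 and 100), `goal24` (goal 24 with options A(6, 1/3), B(6, 0.3) and
#' C(4, 0.5)), and `kt` (the classic paired lottery options (4000, 0.2),
#' (3000, 0.25), (4000, 0.8), (3000, 1) with goals 12000 and 24000).
#'
#' @param kind `"standard"`, `"goal24"` or `"kt"`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
make_fixtures <- function(kind = c("standard", "goal24", "kt"), out_dir = ".") {
  kind <- match.arg(kind)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(game, name) {
    p <- file.path(out_dir, paste0(name, ".json"))
    write_game_json(game, p)
    paths <<- c(paths, p)
  }
  if (kind == "standard") {
    for (g in c(10, 50, 100)) emit(standard_game(g), paste0("standard_g", g))
  } else if (kind == "goal24") {
    # A and B share a utility (distinct probabilities), so they define two
    # alternative goal-24 games, each paired with C
    emit(decision_game(
      data.frame(label = c("A", "C"), u = c(6, 4), p = c(1 / 3, 0.5)),
      goal = 24
    ), "goal24_AC")
    emit(decision_game(
      data.frame(label = c("B", "C"), u = c(6, 4), p = c(0.3, 0.5)),
      goal = 24
    ), "goal24_BC")
  } else {
    kt <- data.frame(
      label = c("A", "B", "C", "D"),
      u = c(4000, 3000, 4000, 3000),
      p = c(0.2, 0.25, 0.8, 1)
    )
    for (goal in c(12000, 24000)) {
      # split into the two classic problems (A vs B, C vs D)
      emit(
        decision_game(kt[1:2, ], goal = goal),
        paste0("kt_AB_goal", goal)
      )
      emit(
        decision_game(kt[3:4, ], goal = goal),
        paste0("kt_CD_goal", goal)
      )
    }
  }
  invisible(paths)
}
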