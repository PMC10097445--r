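# Internal helpers shared across modules.

#' Canonical activity labels
#'
#' The six instructed seated/ambulatory chest movements, in the canonical
#' order used everywhere in the package (confusion matrices, count tables,
#' class indices of the classifier).
#'
#' @return Character vector of length six:
#'   `walk`, `stand_sit`, `rotate`, `swing`, `rock`, `still`.
#' @export
activity_levels <- function() {
  c("walk", "stand_sit", "rotate", "swing", "rock", "still")
}

# Coerce a label vector to a factor over the canonical levels, erroring on
# anything outside them.
as_activity_factor <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), activity_levels())
  if (length(bad) > 0L) {
    stop("unknown activity label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(labels, levels = activity_levels())
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# state. All stochastic operations in the package route through this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a sub-seed (kept below 2^31) from a parent seed
# and a string tag, so pipeline stages and per-subject streams get
# independent but reproducible RNG.
derive_seed <- function(seed, tag) {
  codes <- utf8ToInt(as.character(tag))
  h <- as.double(seed) %% 2147483647
  for (c in codes) h <- (h * 131 + c) %% 2147483647
  as.integer(h %% 2147483629 + 1)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(name, " must be a single positive number", call. = FALSE)
  }
  invisible(TRUE)
}
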