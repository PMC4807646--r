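#' Declare a variable within a block ordering
#'
#' A variable specification carries the information the pipeline needs to
#' place a variable in the block ordering and to transform it: the box it
#' belongs to, whether the box holds joint responses or context (background)
#' variables, and whether the variable is analysed on the natural-log scale.
#'
#' @param name Variable name (must match a cohort column).
#' @param box_index Non-negative integer; 0 is the ultimate-response box and
#'   indices increase toward the background (context) boxes.
#' @param box_kind Either `"response"` or `"context"`.
#' @param log_transform Should the variable be replaced by its natural log
#'   before analysis? Implies `positive_required`.
#' @param units Free-text units, carried as a label only (never converted).
#' @param positive_required Must all observed values be strictly positive?
#' @return An object of class `variable_spec`.
#' @export
variable_spec <- function(name, box_index, box_kind = c("response", "context"),
                          log_transform = TRUE, units = "",
                          positive_required = log_transform) {
  box_kind <- match.arg(box_kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  box_index <- as.integer(box_index)
  if (is.na(box_index) || box_index < 0L)
    stop("`box_index` must be a non-negative integer", call. = FALSE)
  if (log_transform && !positive_required)
    stop("`log_transform` implies `positive_required`", call. = FALSE)
  structure(
    list(name = name, box_index = box_index, box_kind = box_kind,
         log_transform = isTRUE(log_transform), units = units,
         positive_required = isTRUE(positive_required)),
    class = "variable_spec")
}

#' Build a block ordering from boxes of variables
#'
#' The block ordering is the a-priori structure of the analysis: an ordered
#' list of boxes, each holding either joint response variables or context
#' (background) variables. Box 0 contains the ultimate responses; box indices
#' increase toward the background. Admissible explanatory variables for a
#' response are exactly the variables in strictly later boxes.
#'
#' @param boxes A list of boxes; each box is a list of [variable_spec()]
#'   objects (their `box_index`/`box_kind` may be omitted at construction and
#'   are overwritten by the position and `kind` given here).
#' @param kinds Character vector, one of `"response"`/`"context"` per box.
#' @return An object of class `block_ordering` with elements `boxes` (list of
#'   character vectors of names), `variables` (named list of `variable_spec`).
#' @export
block_ordering <- function(boxes, kinds) {
  if (length(boxes) == 0L) stop("ordering must contain at least one box", call. = FALSE)
  if (length(kinds) != length(boxes))
    stop("`kinds` must give one kind per box", call. = FALSE)
  kinds <- match.arg(kinds, c("response", "context"), several.ok = TRUE)
  vars <- list()
  box_names <- vector("list", length(boxes))
  for (b in seq_along(boxes)) {
    box <- boxes[[b]]
    if (length(box) == 0L) stop("boxes must be non-empty", call. = FALSE)
    nm <- character(0)
    for (v in box) {
      v$box_index <- b - 1L
      v$box_kind <- kinds[b]
      v <- variable_spec(v$name, v$box_index, v$box_kind, v$log_transform,
                         v$units %||% "", v$positive_required %||% v$log_transform)
      if (v$name %in% names(vars))
        stop("duplicate variable name: ", v$name, call. = FALSE)
      vars[[v$name]] <- v
      nm <- c(nm, v$name)
    }
    box_names[[b]] <- nm
  }
  # context boxes must carry the highest box indices
  kind_runs <- rle(kinds)
  if (any(kinds == "context")) {
    if (!identical(tail(kind_runs$values, 1L), "context") ||
        sum(kind_runs$values == "context") > 1L)
      stop("context boxes must come after all response boxes", call. = FALSE)
    if (!any(kinds == "response"))
      stop("at least one response box must precede any context box", call. = FALSE)
  }
  structure(list(boxes = box_names, kinds = kinds, variables = vars),
            class = "block_ordering")
}

#' @export
print.block_ordering <- function(x, ...) {
  cat("Block ordering with", length(x$boxes), "boxes (box 0 = ultimate responses):\n")
  for (b in seq_along(x$boxes)) {
    cat(sprintf("  [%d, %s] %s\n", b - 1L, x$kinds[b],
                paste(x$boxes[[b]], collapse = ", ")))
  }
  invisible(x)
}

ordering_names <- function(ordering) names(ordering$variables)

box_index_of <- function(ordering, name) {
  v <- ordering$variables[[name]]
  if (is.null(v)) stop("unknown variable: ", name, call. = FALSE)
  v$box_index
}

box_kind_of <- function(ordering, name) ordering$variables[[name]]$box_kind

#' Read a block-ordering configuration file
#'
#' The configuration is YAML or JSON with a top-level `boxes` list in
#' response-to-background order; each box has `kind` (`response`/`context`)
#' and `variables`, a list of entries with `name`, optional `log` (default
#' true) and optional `units`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [block_ordering()].
#' @export
read_ordering <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$boxes)) stop("config must have a top-level `boxes` list", call. = FALSE)
  boxes <- lapply(cfg$boxes, function(box) {
    lapply(box$variables, function(v) {
      lg <- if (is.null(v$log)) TRUE else isTRUE(v$log)
      variable_spec(v$name, 0L, "response", log_transform = lg,
                    units = v$units %||% "")
    })
  })
  kinds <- vapply(cfg$boxes, function(box) box$kind %||% "response", character(1))
  block_ordering(boxes, kinds)
}

#' Write a block ordering to a YAML configuration file
#'
#' @param ordering A [block_ordering()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ordering <- function(ordering, path) {
  boxes <- lapply(seq_along(ordering$boxes), function(b) {
    list(kind = ordering$kinds[b],
         variables = lapply(ordering$boxes[[b]], function(nm) {
           v <- ordering$variables[[nm]]
           list(name = v$name, log = v$log_transform, units = v$units)
         }))
  })
  yaml::write_yaml(list(boxes = boxes), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
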