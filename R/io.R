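#' Read a provider set from a delimited text table
#'
#' Reads provider quality profiles from a CSV/TSV file in either long form
#' (one row per provider x category) or wide form (one row per provider,
#' one proportion column per category). Category order is always taken
#' from the supplied scale, never from file order. Proportions and weights
#' are validated and renormalized by [provider_set()].
#'
#' @param path Path to a delimited text file with a header row.
#' @param scale A [quality_scale()] giving the ordered categories.
#' @param schema Named list mapping the canonical column roles to the
#'   file's column names. Roles: `provider_id`, `group_id` (optional),
#'   `weight` (optional), `n_responses` (optional), and either `category` +
#'   `proportion` (long form) or `proportions` = character vector of Q
#'   column names in scale order (wide form). Defaults assume canonical
#'   names (`provider_id`, `group_id`, `category`, `proportion`, `weight`,
#'   `n_responses`).
#' @param sep Field separator (default `","`).
#' @return A [provider_set()].
#' @export
read_provider_set <- function(path, scale, schema = list(), sep = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  defaults <- list(provider_id = "provider_id", group_id = "group_id",
                   category = "category", proportion = "proportion",
                   weight = "weight", n_responses = "n_responses")
  unknown <- setdiff(names(schema), c(names(defaults), "proportions"))
  if (length(unknown)) {
    stop(sprintf("unknown schema role(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  sch <- utils::modifyList(defaults, schema)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- function(col, role) {
    if (!col %in% names(df)) {
      stop(sprintf("schema error: column '%s' (role %s) not in file", col, role),
           call. = FALSE)
    }
    df[[col]]
  }
  wide <- !is.null(schema$proportions)
  ids_col <- need(sch$provider_id, "provider_id")

  if (wide) {
    prop_cols <- schema$proportions
    if (length(prop_cols) != scale$Q) {
      stop("wide schema must list exactly Q proportion columns", call. = FALSE)
    }
    for (pc in prop_cols) need(pc, "proportions")
    if (anyDuplicated(ids_col)) stop("duplicate provider rows in wide table", call. = FALSE)
    M <- as.matrix(df[, prop_cols])
    rownames(M) <- as.character(ids_col)
    ord <- seq_len(nrow(df))
  } else {
    cat_col <- as.character(need(sch$category, "category"))
    prop_col <- as.numeric(need(sch$proportion, "proportion"))
    bad <- !cat_col %in% as.character(scale$levels)
    if (any(bad)) {
      stop(sprintf("category '%s' not on the declared scale", cat_col[bad][1]),
           call. = FALSE)
    }
    ids <- unique(as.character(ids_col))
    M <- matrix(0, length(ids), scale$Q,
                dimnames = list(ids, as.character(scale$levels)))
    rows <- cbind(match(as.character(ids_col), ids),
                  match(cat_col, as.character(scale$levels)))
    if (anyDuplicated(rows)) {
      stop("duplicate provider x category rows", call. = FALSE)
    }
    M[rows] <- prop_col
    ord <- match(ids, as.character(ids_col))  # first row of each provider
  }

  per_provider <- function(role) {
    col <- sch[[role]]
    if (!col %in% names(df)) return(NULL)
    v <- df[[col]][ord]
    if (!wide) {
      # long form: the value must be constant within provider
      full <- split(df[[col]], as.character(ids_col))
      nuniq <- vapply(full, function(z) length(unique(z)), integer(1))
      if (any(nuniq > 1)) {
        stop(sprintf("column '%s' varies within a provider", col), call. = FALSE)
      }
    }
    v
  }
  grp <- per_provider("group_id")
  w <- per_provider("weight")
  nresp <- per_provider("n_responses")

  provider_set(mass = M, weight = w,
               group = if (!is.null(grp)) as.character(grp),
               scale = scale, n_responses = nresp)
}

#' Write a provider set as a long CSV table
#'
#' @param ps A [provider_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_provider_set <- function(ps, path) {
  Q <- ps$scale$Q
  ids <- provider_ids(ps)
  df <- data.frame(
    provider_id = rep(ids, each = Q),
    group_id = rep(unname(ps$group), each = Q),
    category = rep(as.character(ps$scale$levels), times = length(ids)),
    proportion = as.vector(t(ps$mass)),
    weight = rep(unname(ps$weight), each = Q),
    stringsAsFactors = FALSE
  )
  if (!is.null(ps$n_responses)) {
    df$n_responses <- rep(unname(ps$n_responses), each = Q)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' A run configuration carries the scale definition (ordered category
#' labels), the column schema, the regression link, the rescale mode and
#' bootstrap settings used by the command-line interface. Unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of class `run_config` with elements `scale` (a
#'   [quality_scale()]), `schema`, `link`, `rescale`, `bootstrap`,
#'   `seed`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("scale", "schema", "link", "rescale", "bootstrap", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(raw$scale) || is.null(raw$scale$levels)) {
    stop("config must define scale: levels", call. = FALSE)
  }
  kind <- if (is.null(raw$scale$kind)) "ordinal" else raw$scale$kind
  sc <- quality_scale(raw$scale$levels, kind = kind)
  structure(
    list(
      scale = sc,
      schema = if (is.null(raw$schema)) list() else raw$schema,
      link = if (is.null(raw$link)) "lpdrm" else match.arg(raw$link, c("lpdrm", "gldrm")),
      rescale = if (is.null(raw$rescale)) "multiplicative"
                else match.arg(raw$rescale, c("multiplicative", "additive", "none")),
      bootstrap = if (is.null(raw$bootstrap)) 0L else as.integer(raw$bootstrap),
      seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed)
    ),
    class = "run_config"
  )
}
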