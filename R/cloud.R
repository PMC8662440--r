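#' Construct a point cloud
#'
#' A point cloud is an ordinary data frame with coordinate columns `x`, `y`,
#' `z` in meters and optional per-point columns: `zn` (height above ground
#' after [normalize_heights()]), `class` (`"ground"`, `"vegetation"` or
#' `"noise"`), and `tree_id` (source tree, 0 for non-tree points; available
#' for simulated clouds).
#'
#' @param x,y,z numeric coordinate vectors (meters).
#' @param ... further per-point columns of the same length (e.g. `tree_id`).
#' @return a `data.frame` of class `point_cloud`.
#' @export
#' @examples
#' pc <- point_cloud(runif(10), runif(10), runif(10))
point_cloud <- function(x, y, z, ...) {
  df <- data.frame(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   ...)
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
    stop("point coordinates must be finite")
  class(df) <- c("point_cloud", "data.frame")
  df
}

as_point_cloud <- function(df) {
  stopifnot(all(c("x", "y", "z") %in% names(df)))
  if (!inherits(df, "point_cloud")) class(df) <- c("point_cloud", "data.frame")
  df
}

#' Read a whitespace-delimited XYZ point cloud
#'
#' Expects one point per line: `x y z` followed by optional extra columns.
#' If a fourth column is present it is interpreted as `tree_id`.
#'
#' @param path file path.
#' @param col_names optional names for columns beyond the first three.
#' @return a [point_cloud()].
#' @export
read_xyz <- function(path, col_names = NULL) {
  df <- utils::read.table(path, header = FALSE)
  if (ncol(df) < 3) stop("XYZ file must have at least three columns")
  nm <- c("x", "y", "z")
  extra <- ncol(df) - 3
  if (extra > 0) {
    if (is.null(col_names)) {
      col_names <- if (extra == 1) "tree_id" else paste0("v", seq_len(extra))
    }
    nm <- c(nm, col_names)
  }
  names(df) <- nm
  as_point_cloud(df)
}

#' Write a point cloud as whitespace-delimited XYZ
#'
#' @param cloud a [point_cloud()].
#' @param path output file path.
#' @param columns columns to write, default `x y z` plus `tree_id` if present.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(cloud, path, columns = NULL) {
  if (is.null(columns)) {
    columns <- c("x", "y", "z")
    if ("tree_id" %in% names(cloud)) columns <- c(columns, "tree_id")
  }
  utils::write.table(cloud[, columns, drop = FALSE], path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

# run code under a temporary RNG state so generators are deterministic by
# seed without clobbering the caller's stream
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}
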