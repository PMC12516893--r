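#' Construct a tridimensional pooling scheme
#'
#' Families are placed on a `cube_dim` x `cube_dim` x `cube_dim` grid and each
#' grid axis is pooled: every row (R), column (C) and depth layer (D) of the
#' cube forms one DNA pool, so each family belongs to exactly three pools and
#' a variant present in one family lights up one pool per axis. Family `i`
#' occupies cell `(r, c, d)` with `i = r*cube_dim^2 + c*cube_dim + d`
#' (row-major); partially filled cubes fill cells in index order.
#'
#' The platform-scale screen places 512 M2 families on an 8x8x8 cube, giving
#' 24 pools of 64 families each.
#'
#' @param n_families Number of families to place (`1 <= n_families <=
#'   cube_dim^3`). Family ids are 0-based integers `0:(n_families-1)`.
#' @param cube_dim Families per cube axis.
#' @return A `pooling_scheme`: list with `cube_dim`, `n_families`, `cells`
#'   (data.frame `family_id`, `r`, `c`, `d`) and `pool_labels`.
#' @examples
#' sc <- build_scheme(512, 8)
#' length(sc$pool_labels)              # 24 pools
#' length(pool_members(sc, "R0"))      # 64 families
#' @export
build_scheme <- function(n_families, cube_dim) {
  if (length(cube_dim) != 1L || is.na(cube_dim) || cube_dim < 1)
    stop("`cube_dim` must be a single integer >= 1", call. = FALSE)
  cube_dim <- as.integer(cube_dim)
  if (length(n_families) != 1L || is.na(n_families) || n_families < 1)
    stop("`n_families` must be a single integer >= 1", call. = FALSE)
  n_families <- as.integer(n_families)
  if (n_families > cube_dim^3)
    stop(sprintf("capacity exceeded: %d families do not fit a %d^3 cube (max %d)",
                 n_families, cube_dim, cube_dim^3), call. = FALSE)
  i <- 0:(n_families - 1L)
  cells <- data.frame(
    family_id = i,
    r = i %/% cube_dim^2,
    c = (i %/% cube_dim) %% cube_dim,
    d = i %% cube_dim
  )
  structure(
    list(
      cube_dim = cube_dim,
      n_families = n_families,
      cells = cells,
      pool_labels = c(paste0("R", 0:(cube_dim - 1L)),
                      paste0("C", 0:(cube_dim - 1L)),
                      paste0("D", 0:(cube_dim - 1L)))
    ),
    class = "pooling_scheme"
  )
}

#' @export
print.pooling_scheme <- function(x, ...) {
  cat(sprintf("Tridimensional pooling scheme: %d families on a %d^3 cube, %d pools\n",
              x$n_families, x$cube_dim, length(x$pool_labels)))
  invisible(x)
}

#' Pools containing a family
#'
#' @param scheme A [build_scheme()] result.
#' @param family_id A single 0-based family id registered in the scheme.
#' @return Named character vector of the R, C and D pool labels.
#' @examples
#' pools_of(build_scheme(512, 8), 175)   # R2 C5 D7
#' @export
pools_of <- function(scheme, family_id) {
  stopifnot(inherits(scheme, "pooling_scheme"))
  row <- scheme$cells[match(family_id, scheme$cells$family_id), ]
  if (any(is.na(row$family_id)))
    stop(sprintf("unknown family id: %s", paste(family_id, collapse = ", ")),
         call. = FALSE)
  c(R = paste0("R", row$r), C = paste0("C", row$c), D = paste0("D", row$d))
}

#' Families contained in a pool
#'
#' @inheritParams pools_of
#' @param pool A pool label such as `"R0"`, `"C3"`, `"D7"`.
#' @return Integer vector of family ids.
#' @export
pool_members <- function(scheme, pool) {
  stopifnot(inherits(scheme, "pooling_scheme"))
  if (!pool %in% scheme$pool_labels)
    stop(sprintf("unknown pool label '%s'", pool), call. = FALSE)
  axis <- substr(pool, 1L, 1L)
  idx <- as.integer(substr(pool, 2L, nchar(pool)))
  col <- c(R = "r", C = "c", D = "d")[[axis]]
  scheme$cells$family_id[scheme$cells[[col]] == idx]
}

#' Deconvolve a positive-pool pattern to candidate families
#'
#' Candidates are the intersection, over axes that have at least one positive
#' pool, of the union of the memberships of that axis's positive pools.
#' Status is `"unique"` (one candidate), `"ambiguous"` (several candidates,
#' all axes represented), `"incomplete"` (at least one axis has no positive
#' pool) or `"empty"` (all axes represented but the intersection is empty).
#'
#' @inheritParams pools_of
#' @param positive_pools Character vector of pool labels (possibly empty).
#' @return A `deconvolution_result`: list with `candidate_family_ids`,
#'   `status` and `positive_pools`.
#' @examples
#' sc <- build_scheme(512, 8)
#' deconvolve(sc, c("R2", "C5", "D7"))$candidate_family_ids   # 175
#' @export
deconvolve <- function(scheme, positive_pools) {
  stopifnot(inherits(scheme, "pooling_scheme"))
  positive_pools <- unique(as.character(positive_pools))
  bad <- setdiff(positive_pools, scheme$pool_labels)
  if (length(bad))
    stop(sprintf("unknown pool label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  axes <- c("R", "C", "D")
  by_axis <- lapply(axes, function(a)
    positive_pools[substr(positive_pools, 1L, 1L) == a])
  names(by_axis) <- axes
  present <- vapply(by_axis, function(p) length(p) > 0L, logical(1))
  cand <- scheme$cells$family_id
  for (a in axes[present]) {
    members <- unique(unlist(lapply(by_axis[[a]], pool_members,
                                    scheme = scheme)))
    cand <- intersect(cand, members)
  }
  status <- if (!all(present)) "incomplete"
            else if (length(cand) == 1L) "unique"
            else if (length(cand) == 0L) "empty"
            else "ambiguous"
  structure(
    list(candidate_family_ids = sort(cand), status = status,
         positive_pools = positive_pools),
    class = "deconvolution_result"
  )
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat(sprintf("Deconvolution: status=%s, %d candidate(s) [pools: %s]\n",
              x$status, length(x$candidate_family_ids),
              paste(x$positive_pools, collapse = ",")))
  invisible(x)
}

#' Write / read a pooling scheme as TSV
#'
#' Columns: `family_id`, `r`, `c`, `d`, `pool_R`, `pool_C`, `pool_D`
#' (0-based indices, header required).
#'
#' @inheritParams pools_of
#' @param path File path.
#' @return `write_scheme_tsv()` returns `path` invisibly; `read_scheme_tsv()`
#'   returns a `pooling_scheme`.
#' @export
write_scheme_tsv <- function(scheme, path) {
  stopifnot(inherits(scheme, "pooling_scheme"))
  df <- scheme$cells
  df$pool_R <- paste0("R", df$r)
  df$pool_C <- paste0("C", df$c)
  df$pool_D <- paste0("D", df$d)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scheme_tsv
#' @export
read_scheme_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("family_id", "r", "c", "d")
  if (!all(need %in% names(df)))
    stop("scheme TSV must have columns family_id, r, c, d", call. = FALSE)
  dim_guess <- max(df$r, df$c, df$d) + 1L
  sc <- build_scheme(nrow(df), dim_guess)
  # verify the file matches the canonical row-major layout
  if (!all(sc$cells$r == df$r & sc$cells$c == df$c & sc$cells$d == df$d))
    stop("scheme TSV does not follow the row-major family->cell convention",
         call. = FALSE)
  sc
}
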