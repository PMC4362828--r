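# Minting of policy-conformant term URIs.
#
# OBO-style term URIs concatenate a start portion (e.g. the OBO PURL base
# "http://purl.obolibrary.org/obo/"), a prefix ("VO_") and a fixed-width
# zero-padded number. The allocator hands out the smallest eligible number
# at or above the configured start, skipping numbers already present in the
# target ontology: incrementally assigned IDs could otherwise silently
# duplicate existing terms. Numeric parts are held as doubles; with at most
# 18 digits the values used in practice stay well inside exact integer
# range.

#' Allocation state for ID minting
#'
#' @param policy an [id_policy()].
#' @param used numeric vector of ID numbers already taken (typically from
#'   [scan_existing_ids()] on the target ontology). Allocation never
#'   returns any of these.
#' @return an environment of class `id_state` with fields `policy`, `used`
#'   (an environment used as a set) and `cursor`.
#' @export
id_state <- function(policy, used = numeric(0)) {
  stopifnot(inherits(policy, "id_policy"))
  st <- new.env(parent = emptyenv())
  st$policy <- policy
  st$used <- new.env(parent = emptyenv())
  for (n in used) assign(sprintf("%.0f", n), TRUE, envir = st$used)
  st$cursor <- policy$start
  class(st) <- "id_state"
  st
}

#' @export
print.id_state <- function(x, ...) {
  cat(sprintf("<id_state: prefix=%s digits=%d cursor=%.0f, %d used>\n",
              x$policy$prefix, x$policy$digits, x$cursor,
              length(ls(x$used))))
  invisible(x)
}

zero_pad <- function(n, digits) {
  s <- sprintf("%.0f", n)
  if (nchar(s) > digits) {
    stop(sprintf("number %s does not fit in %d digits", s, digits), call. = FALSE)
  }
  paste0(strrep("0", digits - nchar(s)), s)
}

#' Allocate the next local ID
#'
#' Returns `prefix` + the smallest eligible number `>= cursor` zero-padded
#' to the policy's width, marks it used and advances the cursor. Numbers in
#' the used set are skipped (gap-filling above `start`); numbers below
#' `start` are never assigned.
#'
#' @param state an [id_state()]; modified in place.
#' @return the local ID string, e.g. `"VO_0010000"`.
#' @export
allocate <- function(state) {
  stopifnot(inherits(state, "id_state"))
  limit <- 10^state$policy$digits
  n <- state$cursor
  while (n < limit &&
         exists(sprintf("%.0f", n), envir = state$used, inherits = FALSE)) {
    n <- n + 1
  }
  if (n >= limit) {
    stop(sprintf(
      "ID capacity exhausted: no free %d-digit number at or above %.0f remains",
      state$policy$digits, state$cursor), call. = FALSE)
  }
  assign(sprintf("%.0f", n), TRUE, envir = state$used)
  state$cursor <- n + 1
  paste0(state$policy$prefix, zero_pad(n, state$policy$digits))
}

#' Scan a target ontology for IDs already in use
#'
#' Extracts the numeric part of every entity URI of the exact shape
#' `uri_start` + `policy$prefix` + an exactly `policy$digits`-digit number.
#' Classes, object properties and annotation properties are all scanned:
#' any entity URI can collide with a would-be minted one.
#'
#' @param snapshot an `ontology_snapshot` from [load_ontology()].
#' @param policy an [id_policy()].
#' @param uri_start the URI start portion new terms will be minted under.
#' @return numeric vector of ID numbers found (possibly empty).
#' @export
scan_existing_ids <- function(snapshot, policy, uri_start) {
  stopifnot(inherits(snapshot, "ontology_snapshot"),
            inherits(policy, "id_policy"))
  pat <- paste0("^",
                gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                     paste0(uri_start, policy$prefix)),
                "([0-9]{", policy$digits, "})$")
  uris <- snapshot$entity_uris
  m <- regmatches(uris, regexec(pat, uris))
  nums <- vapply(m, function(x) if (length(x) == 2L) as.numeric(x[[2]]) else NA_real_,
                 numeric(1))
  sort(unique(nums[!is.na(nums)]))
}

#' Mint a full term URI
#'
#' @param uri_start absolute URI prefix (the start portion).
#' @param local_id local ID string, e.g. `"VO_0010000"`.
#' @return `uri_start` concatenated with `local_id`.
#' @export
mint_uri <- function(uri_start, local_id) {
  if (!is_absolute_uri(uri_start)) {
    stop("uri_start must be an absolute URI, got: ", deparse(uri_start),
         call. = FALSE)
  }
  paste0(uri_start, local_id)
}
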