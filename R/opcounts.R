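#' Primitive-operation counters
#'
#' Every cryptographic primitive increments a package-level counter when it
#' runs: PRF evaluations (`prf`), group exponentiations (`group_exp`), hash
#' evaluations (`hash`), trapdoor permutation evaluations (`tp_forward`,
#' `tp_inverse`) and symmetric encryptions/decryptions (`se_encrypt`,
#' `se_decrypt`). These counters make the closed-form per-operation cost
#' contracts of the scheme directly testable: costs are stated in primitive
#' operations, not wall-clock time, because only the former are
#' hardware-independent.
#'
#' @return `op_counts()` returns a named integer vector of counts since the
#'   last reset; `op_reset()` resets all counters to zero (invisibly).
#' @examples
#' op_reset()
#' op_counts()
#' @export
op_counts <- function() {
  unlist(as.list(.op, all.names = FALSE))[.op_names]
}

#' @rdname op_counts
#' @export
op_reset <- function() {
  for (nm in .op_names) assign(nm, 0L, envir = .op)
  invisible(NULL)
}

#' @rdname op_counts
#' @param expr Expression to evaluate with fresh counters.
#' @return `with_op_counts(expr)` returns `list(value = <result of expr>,
#'   counts = <named integer vector>)`; counters outside the call are
#'   restored afterwards, so nested measurements do not interfere.
#' @export
with_op_counts <- function(expr) {
  saved <- op_counts()
  op_reset()
  on.exit({
    for (nm in .op_names) assign(nm, saved[[nm]], envir = .op)
  })
  value <- force(expr)
  list(value = value, counts = op_counts())
}

.op_names <- c("prf", "group_exp", "hash", "tp_forward", "tp_inverse",
               "se_encrypt", "se_decrypt")
.op <- new.env(parent = emptyenv())
for (nm in .op_names) assign(nm, 0L, envir = .op)

op_tick <- function(name) {
  assign(name, get(name, envir = .op) + 1L, envir = .op)
  invisible(NULL)
}

#' Closed-form predicted operation counts
#'
#' Predicted primitive-operation counts per protocol phase, split by role.
#' For adding one owner with `x` keywords the client performs `2 + 2x` PRFs,
#' `2x` group exponentiations, `x` hashes, `x` trapdoor inversions and `x`
#' symmetric encryptions. Deleting an owner with `x` live keywords costs the
#' client 2 PRFs and the server `x` exponentiations plus `x` hashes. A search
#' on a keyword with counter `c` costs the client 1 PRF and the server `c`
#' exponentiations, `c` hashes and `c - 1` trapdoor forward evaluations.
#'
#' @param phase `"add"`, `"delete"` or `"search"`.
#' @param x Number of keywords of the owner (add/delete phases).
#' @param c Chain counter of the searched keyword (search phase).
#' @return A list with named integer vectors `client` and `server`.
#' @export
predict_op_counts <- function(phase = c("add", "delete", "search"),
                              x = NULL, c = NULL) {
  phase <- match.arg(phase)
  if (!is.null(x)) x <- as.integer(x)
  if (!is.null(c)) c <- as.integer(c)
  zero <- structure(integer(length(.op_names)), names = .op_names)
  cl <- sv <- zero
  if (phase == "add") {
    stopifnot(x >= 1)
    cl["prf"] <- 2L + 2L * x
    cl["group_exp"] <- 2L * x
    cl["hash"] <- x
    cl["tp_inverse"] <- x
    cl["se_encrypt"] <- x
  } else if (phase == "delete") {
    stopifnot(x >= 0)
    cl["prf"] <- 2L
    sv["group_exp"] <- x
    sv["hash"] <- x
  } else {
    stopifnot(c >= 1)
    cl["prf"] <- 1L
    sv["group_exp"] <- c
    sv["hash"] <- c
    sv["tp_forward"] <- c - 1L
  }
  list(client = cl, server = sv)
}
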