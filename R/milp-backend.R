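# Solver backend: formulates go through a single contract, hp_milp(), which
# dispatches to an exact branch-and-bound MIP solver (HiGHS, reached through
# scipy.optimize.milp in a python worker process). The worker is started once
# per R session and answers requests over a localhost socket; if the socket
# path is unavailable the backend falls back to one subprocess per solve.

.solver_state <- new.env(parent = emptyenv())

HP_INF <- 1e30

#' Is the MILP solver backend available?
#'
#' The scheduling models are solved by an exact mixed-integer solver (HiGHS)
#' reached through a `python` worker with `scipy` installed. This checks that
#' `python` resolves on the PATH.
#'
#' @return `TRUE` or `FALSE`.
#' @export
milp_backend_available <- function() {
  nzchar(Sys.which("python")) || nzchar(Sys.which("python3"))
}

python_bin <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) {
    abort(paste0(
      "The MILP backend needs `python` with scipy >= 1.9 on the PATH ",
      "(used for the HiGHS mixed-integer solver)."
    ))
  }
  unname(p)
}

worker_script <- function() {
  path <- system.file("python", "milp_worker.py", package = "harvestplan")
  if (!nzchar(path)) abort("milp_worker.py not found in the installed package")
  path
}

solver_close <- function(...) {
  con <- .solver_state$con
  if (!is.null(con)) {
    try(writeLines("QUIT", con), silent = TRUE)
    try(close(con), silent = TRUE)
  }
  .solver_state$con <- NULL
  invisible(NULL)
}

# Start the persistent worker; returns a connection or NULL on failure.
solver_connect <- function() {
  portfile <- tempfile("hp_milp_port_")
  ok <- tryCatch({
    system2(python_bin(), c(shQuote(worker_script()), "server"),
            stdout = portfile, stderr = FALSE, wait = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) return(NULL)
  port <- NA_integer_
  for (i in seq_len(200L)) {
    if (file.exists(portfile)) {
      line <- tryCatch(readLines(portfile, n = 1L, warn = FALSE),
                       error = function(e) character())
      if (length(line) == 1L && nzchar(line)) {
        port <- suppressWarnings(as.integer(line))
        break
      }
    }
    Sys.sleep(0.05)
  }
  if (is.na(port)) return(NULL)
  con <- tryCatch(
    socketConnection("127.0.0.1", port = port, blocking = TRUE,
                     open = "r+", timeout = 3600),
    error = function(e) NULL, warning = function(w) NULL
  )
  con
}

solver_request <- function(json_line) {
  if (is.null(.solver_state$con) && !isTRUE(.solver_state$no_server)) {
    con <- solver_connect()
    if (is.null(con)) {
      .solver_state$no_server <- TRUE
    } else {
      .solver_state$con <- con
      reg.finalizer(.solver_state, solver_close, onexit = TRUE)
    }
  }
  con <- .solver_state$con
  if (!is.null(con)) {
    ans <- tryCatch({
      writeLines(json_line, con)
      flush(con)
      readLines(con, n = 1L, warn = FALSE)
    }, error = function(e) character())
    if (length(ans) == 1L && nzchar(ans)) return(ans)
    solver_close()  # worker died; fall through to one-shot
  }
  fin <- tempfile("hp_milp_in_", fileext = ".json")
  fout <- tempfile("hp_milp_out_", fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(json_line, fin)
  status <- system2(python_bin(),
                    c(shQuote(worker_script()), "oneshot",
                      shQuote(fin), shQuote(fout)),
                    stdout = FALSE, stderr = FALSE)
  if (!identical(status, 0L) || !file.exists(fout)) {
    abort("MILP worker subprocess failed; is scipy installed for `python`?")
  }
  paste(readLines(fout, warn = FALSE), collapse = "")
}

#' Solve a mixed-integer linear program
#'
#' Low-level entry point of the solver backend contract. Minimises `c'x`
#' subject to `cl <= A x <= cu` and `lb <= x <= ub`, with the variables
#' flagged in `integrality` restricted to integers. Infeasibility is a
#' returned status, never an error.
#'
#' @param obj numeric objective coefficients (minimised).
#' @param A constraint matrix as a list with integer vectors `i`, `j`
#'   (1-based), numeric `v`, and scalars `nrow`, `ncol`; or a dense matrix.
#' @param cl,cu numeric row lower/upper bounds (`-Inf`/`Inf` allowed).
#' @param lb,ub numeric variable bounds; defaults 0 and `Inf`.
#' @param integrality integer/logical vector, 1 where the variable is integer.
#' @param time_limit seconds before the solver gives up, default 600.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"time_limit"`,
#'   `"error"`), `objective`, solution vector `x`, and solver `message`.
#' @export
hp_milp <- function(obj, A, cl, cu,
                    lb = rep(0, length(obj)),
                    ub = rep(Inf, length(obj)),
                    integrality = rep(1L, length(obj)),
                    time_limit = getOption("harvestplan.solver_time_limit", 600)) {
  if (is.matrix(A)) {
    nz <- which(A != 0, arr.ind = TRUE)
    A <- list(i = nz[, 1L], j = nz[, 2L], v = A[nz],
              nrow = nrow(A), ncol = ncol(A))
  }
  stopifnot(length(cl) == A$nrow, length(cu) == A$nrow,
            length(lb) == length(obj), length(ub) == length(obj))
  clip <- function(x) pmax(pmin(x, HP_INF), -HP_INF)
  model <- list(
    c = as.numeric(obj),
    integrality = as.integer(integrality),
    lb = clip(as.numeric(lb)),
    ub = clip(as.numeric(ub)),
    A = list(i = as.integer(A$i) - 1L, j = as.integer(A$j) - 1L,
             v = as.numeric(A$v), nrow = A$nrow, ncol = A$ncol),
    cl = clip(as.numeric(cl)),
    cu = clip(as.numeric(cu)),
    time_limit = time_limit
  )
  json <- jsonlite::toJSON(model, auto_unbox = TRUE, digits = NA)
  res <- jsonlite::fromJSON(solver_request(as.character(json)),
                            simplifyVector = TRUE)
  if (identical(res$status, "error")) {
    abort(paste0("MILP solver error: ", res$message %||% "unknown"))
  }
  list(status = res$status,
       objective = if (!is.null(res$objective)) as.numeric(res$objective),
       x = if (!is.null(res$x)) as.numeric(res$x),
       message = res$message %||% "")
}

.onUnload <- function(libpath) {
  solver_close()
}
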