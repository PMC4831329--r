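#' Load an airway-tree morphometry table
#'
#' Reads a per-generation summary of an airway tree: branch counts, terminal
#' branch counts and diameter statistics (mean, maximum, minimum, standard
#' deviation, all in mm). The packaged default table
#' ([default_morphometry()]) describes a 26-generation asymmetric human
#' airway tree with 32,447 terminal branches.
#'
#' @param path Path to a CSV file with columns `generation`, `branches`,
#'   `terminal_branches`, `d_mean`, `d_max`, `d_min`, `d_std`.
#' @return A data frame of class `morphometry`, one row per generation.
#' @examples
#' m <- default_morphometry()
#' sum(m$terminal_branches)  # 32447
#' @export
load_morphometry <- function(path) {
  if (!file.exists(path)) .stopf("morphometry file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("generation", "branches", "terminal_branches",
                "d_mean", "d_max", "d_min", "d_std")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    .stopf("morphometry file is missing column(s): %s",
           paste(missing, collapse = ", "))
  as_morphometry(tab[required])
}

#' Construct and validate a morphometry table
#'
#' @param tab Data frame with the columns listed in [load_morphometry()].
#' @return The validated table with class `morphometry`.
#' @export
as_morphometry <- function(tab) {
  tab <- as.data.frame(tab)
  g <- tab$generation
  if (any(!is.finite(as.matrix(tab))))
    .stopf("morphometry table contains non-finite values")
  if (!identical(as.integer(g), seq_len(nrow(tab))))
    .stopf("generations must be 1..G in order without gaps")
  if (tab$branches[1L] != 1L)
    .stopf("generation 1 must contain exactly one branch (the trachea)")
  if (any(tab$branches < 1) || any(tab$terminal_branches < 0))
    .stopf("branch counts must be positive and terminal counts non-negative")
  if (any(tab$terminal_branches > tab$branches))
    .stopf("terminal branch count exceeds branch count in generation(s) %s",
           paste(g[tab$terminal_branches > tab$branches], collapse = ", "))
  if (any(tab$d_min <= 0))
    .stopf("all diameters must be positive")
  if (any(tab$d_min > tab$d_mean | tab$d_mean > tab$d_max))
    .stopf("need d_min <= d_mean <= d_max in every generation")
  if (any(tab$d_std < 0)) .stopf("d_std must be non-negative")
  class(tab) <- c("morphometry", "data.frame")
  tab
}

#' Packaged default morphometry table
#'
#' Per-generation branch counts and diameter statistics of the 26-generation
#' asymmetric airway-tree model used as the package's default mechanical
#' substrate (64,893 branches, 32,447 terminal branches; terminals appear
#' from generation 9 onward).
#'
#' @return A `morphometry` data frame with 26 rows.
#' @export
default_morphometry <- function() {
  load_morphometry(system.file("extdata", "airway_morphometry.csv",
                               package = "lungsim", mustWork = TRUE))
}

# Feasibility of a morphometry table under binary branching: children of the
# non-terminal branches of generation g must account for generation g+1.
.check_branching_feasibility <- function(m) {
  G <- nrow(m)
  for (g in seq_len(G - 1L)) {
    open <- m$branches[g] - m$terminal_branches[g]
    nxt <- m$branches[g + 1L]
    if (nxt > 2L * open || nxt < open)
      .stopf(paste0("generation %d has %d branches but generation %d leaves ",
                    "only %d non-terminal parents (binary branching cap)"),
             g + 1L, nxt, g, open)
  }
  if (m$terminal_branches[G] != m$branches[G])
    .stopf("all branches of the last generation must be terminal")
  invisible(TRUE)
}

#' @export
print.morphometry <- function(x, ...) {
  cat(sprintf("Airway morphometry: %d generations, %d branches, %d terminal\n",
              nrow(x), sum(x$branches), sum(x$terminal_branches)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
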