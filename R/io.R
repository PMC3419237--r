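## Tabular and tree IO plus run manifests.

#' Read a Cp table or a primer-efficiency table
#'
#' TSV readers with column validation. The Cp table needs columns
#' `sample_id`, `group`, `tissue`, `gene`, `cp1`, `cp2`; the efficiency
#' table needs `gene`, `tissue`, `E`.
#'
#' @param path file path.
#' @return Data frame.
#' @export
read_cp_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "tissue", "gene", "cp1", "cp2")
  if (!all(need %in% names(df)))
    stop("Cp table ", path, " must have columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname read_cp_table
#' @export
read_efficiencies <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "tissue", "E")
  if (!all(need %in% names(df)))
    stop("efficiency table ", path, " must have columns: ",
         paste(need, collapse = ", "))
  if (any(df$E <= 1 | df$E > 2.1))
    stop("efficiencies in ", path, " must lie in (1, 2.1]")
  df
}

#' Write a data frame as TSV
#'
#' @param df data frame.
#' @param path file path (or `""` for stdout).
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a Newick tree
#'
#' Wrappers around ape's Newick IO that preserve branch lengths and
#' internal-node (support) labels.
#'
#' @param path file path.
#' @return `read_newick()`: an `ape::phylo`.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("malformed Newick in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("malformed Newick in ", path)
  tr
}

#' @param tree an `ape::phylo` (or a `boot_tree`, whose annotated tree is
#'   written).
#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "boot_tree")) tree <- tree$tree
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Append a run manifest
#'
#' Records one JSON line per pipeline run (subcommand, seed, input/output
#' paths, package version, timestamp, MD5 of the config file if any) to an
#' append-only manifest file.
#'
#' @param manifest_path path of the manifest file (created if absent).
#' @param subcommand name of the stage that ran.
#' @param seed RNG seed used, or `NA`.
#' @param inputs,outputs character vectors of paths.
#' @param config_path optional config file to fingerprint.
#' @return Invisibly, the manifest entry as a list.
#' @export
append_run_manifest <- function(manifest_path, subcommand, seed = NA,
                                inputs = character(0), outputs = character(0),
                                config_path = NULL) {
  entry <- list(
    subcommand = subcommand,
    seed = seed,
    inputs = as.character(inputs),
    outputs = as.character(outputs),
    config_md5 = if (!is.null(config_path) && file.exists(config_path))
      unname(tools::md5sum(config_path)) else NA,
    package_version = as.character(utils::packageVersion("rnrkit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  line <- jsonlite::toJSON(entry, auto_unbox = TRUE)
  cat(line, "\n", sep = "", file = manifest_path, append = TRUE)
  invisible(entry)
}
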