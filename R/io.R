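#' Read an nCounter-style count table
#'
#' Two plain-text dialects are supported. \code{"csv"}: a CSV with columns
#' \code{probe_id}, \code{probe_class} and one integer column per sample.
#' \code{"rcc"}: a minimal sectioned dialect in which the block between
#' \code{<Code_Summary>} and \code{</Code_Summary>} holds the same CSV
#' payload (other sections are ignored). Genuine binary RCC archives are out
#' of scope.
#'
#' @param path file path.
#' @param dialect \code{"csv"} or \code{"rcc"}.
#' @return A \linkS4class{MiRCountSet} with integer raw counts and stable
#'   probe/sample order.
#' @export
readCountTable <- function(path, dialect = c("csv", "rcc")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "csv") {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    open <- grep("^<Code_Summary>", lines)
    close <- grep("^</Code_Summary>", lines)
    if (length(open) != 1L || length(close) != 1L || close <= open)
      stop("rcc dialect requires one <Code_Summary> ... </Code_Summary> block")
    df <- read.csv(text = paste(lines[(open + 1L):(close - 1L)],
                                collapse = "\n"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  }
  req <- c("probe_id", "probe_class")
  if (!all(req %in% colnames(df)))
    stop("count table must have 'probe_id' and 'probe_class' columns")
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup))
    stop("duplicate probe id(s): ", paste(unique(dup), collapse = ", "))
  badClass <- which(!df$probe_class %in% .PROBE_CLASSES)
  if (length(badClass))
    stop(sprintf("unknown probe class '%s' at row %d (probe %s)",
                 df$probe_class[badClass[1L]], badClass[1L],
                 df$probe_id[badClass[1L]]))
  cts <- as.matrix(df[, setdiff(colnames(df), req), drop = FALSE])
  if (!is.numeric(cts)) stop("sample columns must be numeric")
  neg <- which(cts < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative count for probe %s, sample %s",
                 df$probe_id[neg[1L, 1L]], colnames(cts)[neg[1L, 2L]]))
  if (any(cts != round(cts)))
    stop("raw counts must be integers")
  storage.mode(cts) <- "integer"
  rownames(cts) <- df$probe_id
  MiRCountSet(cts, probeClass = df$probe_class)
}

#' Read a cell-fraction or leukocyte-differential CSV
#'
#' Expects a \code{sample} column plus one numeric column per cell type or
#' leukocyte class; values may be percentages or proportions (rows are
#' renormalised to sum to one).
#'
#' @param path file path.
#' @return A \linkS4class{CellFractions}.
#' @export
readFractionTable <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample" %in% colnames(df)) stop("'sample' column required")
  m <- as.matrix(df[, setdiff(colnames(df), "sample"), drop = FALSE])
  rownames(m) <- df$sample
  CellFractions(m, source = "file")
}

#' Read an RT-qPCR Ct table
#'
#' @param path CSV with columns sample, assay, class (target/reference),
#'   replicate, ct.
#' @return data.frame.
#' @export
readCtTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample", "assay", "class", "replicate", "ct")
  if (!all(req %in% colnames(df)))
    stop("Ct table must have columns: ", paste(req, collapse = ", "))
  if (any(df$ct <= 0)) stop("Ct values must be positive")
  key <- paste(df$sample, df$assay, df$replicate)
  if (anyDuplicated(key))
    stop("replicate indices must be unique within (sample, assay)")
  df
}

#' Read a subject demographics table
#'
#' Mirrors the printed cohort table: one row per subject with age, sex,
#' allergen and pre/post methacholine PC20 (mg/ml). The string \code{"ND"}
#' or an empty field marks a value that was not determined and is read as
#' \code{NA}.
#'
#' @param path CSV with columns subject, group, age, sex, allergen,
#'   pc20_pre, pc20_post.
#' @return data.frame with numeric PC20 columns.
#' @export
readSubjectTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 na.strings = c("ND", "NA", ""))
  req <- c("subject", "group", "age", "pc20_pre", "pc20_post")
  if (!all(req %in% colnames(df)))
    stop("subject table must have columns: ", paste(req, collapse = ", "))
  df$pc20_pre <- as.numeric(df$pc20_pre)
  df$pc20_post <- as.numeric(df$pc20_post)
  if (any(stats::na.omit(c(df$pc20_pre, df$pc20_post)) <= 0))
    stop("PC20 values must be positive where present")
  hc <- df$group == "HC"
  if (any(!is.na(df$pc20_pre[hc]) | !is.na(df$pc20_post[hc])))
    stop("healthy-control records must not carry PC20 values")
  df
}

#' Bundled example subject demographics
#'
#' The demographics of the worked example: seven mild atopic asthmatic
#' subjects undergoing cat-allergen inhalation challenge (with pre/post
#' methacholine PC20) and four healthy controls.
#'
#' @return data.frame as from \code{\link{readSubjectTable}}.
#' @export
exampleSubjects <- function() {
  readSubjectTable(system.file("extdata", "table1_subjects.csv",
                               package = "bloodmiR", mustWork = TRUE))
}

#' Bundled example leukocyte differentials
#'
#' Group mean (and standard error) percentages of the five leukocyte classes
#' for healthy controls and the pre-/post-challenge asthmatic groups, used
#' to anchor the simulator's cell-fraction distribution and as the worked
#' example for fraction grouping.
#'
#' @return data.frame with one row per group.
#' @export
exampleDifferentials <- function() {
  read.csv(system.file("extdata", "table2_differentials.csv",
                       package = "bloodmiR", mustWork = TRUE),
           stringsAsFactors = FALSE)
}
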