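#' Build a membrane antibody-array layout
#'
#' Lays analytes out on a letter-row / numbered-column grid, each analyte as
#' a group of `dup` adjacent duplicate spots, followed by positive (POS) and
#' negative (NEG) control spots; remaining grid positions are BLANK. The
#' layout mimics commercial cytokine membranes where POS spots carry a
#' constant high deposit used for between-membrane scaling and NEG spots
#' measure chemiluminescent background.
#'
#' @param n_analytes Number of analytes (default 80).
#' @param analyte_names Optional character vector of analyte names.
#' @param n_cols Grid columns per row (default 10).
#' @param n_pos,n_neg Number of POS / NEG control spots (default 4 each).
#' @param dup Duplicate spots per analyte (default 2).
#' @return A data frame with columns `row` (letter), `col` (integer),
#'   `name`, `role` (`analyte`/`POS`/`NEG`/`BLANK`) and `dup_group`.
#' @examples
#' head(make_array_layout(n_analytes = 6, n_cols = 4))
#' @export
make_array_layout <- function(n_analytes = 80L, analyte_names = NULL,
                              n_cols = 10L, n_pos = 4L, n_neg = 4L,
                              dup = 2L) {
  if (is.null(analyte_names)) {
    analyte_names <- sprintf("CYT%02d", seq_len(n_analytes))
  }
  stopifnot(length(analyte_names) == n_analytes, !anyDuplicated(analyte_names),
            n_pos >= 1L)
  n_spots <- n_analytes * dup + n_pos + n_neg
  n_rows <- ceiling(n_spots / n_cols)
  total <- n_rows * n_cols
  row_letters <- make.unique(c(LETTERS, paste0(LETTERS, "A")))[seq_len(n_rows)]

  name <- c(rep(analyte_names, each = dup),
            rep("POS", n_pos), rep("NEG", n_neg),
            rep("BLANK", total - n_spots))
  role <- c(rep("analyte", n_analytes * dup),
            rep("POS", n_pos), rep("NEG", n_neg),
            rep("BLANK", total - n_spots))
  dup_group <- name
  data.frame(
    row = rep(row_letters, each = n_cols),
    col = rep(seq_len(n_cols), times = n_rows),
    name = name, role = role, dup_group = dup_group
  )
}

validate_layout <- function(layout) {
  req <- c("row", "col", "name", "role")
  if (!all(req %in% names(layout))) {
    stop("layout must have columns row, col, name, role", call. = FALSE)
  }
  if (!"dup_group" %in% names(layout)) layout$dup_group <- layout$name
  coord <- paste(layout$row, layout$col)
  if (anyDuplicated(coord)) stop("layout coordinates must be unique",
                                 call. = FALSE)
  if (!any(layout$role == "POS")) {
    stop("layout has no POS control spots: normalization impossible",
         call. = FALSE)
  }
  layout
}

#' Simulate raw cytokine-membrane spot intensities
#'
#' Generates one raw spot-intensity table per membrane
#' (`array_replicates_per_group` membranes per condition). Each analyte has
#' a latent normalised abundance; raw spot intensity is
#' `background + value * (pos_level - background)` with multiplicative
#' noise of coefficient of variation `noise_cv` applied independently to
#' every analyte spot (duplicates are noisy copies). POS spots sit at a
#' constant high level and NEG spots at the constant background, so with
#' `noise_cv = 0` the normalisation in [summarize_membrane()] recovers the
#' latent values exactly. A `de_fraction` of analytes carries a planted
#' fold change on the treated membranes.
#'
#' @param config A [sim_config()].
#' @param layout A layout as from [make_array_layout()]; must contain POS
#'   control spots.
#' @param pos_level,background Raw intensity of POS spots and background
#'   (defaults 1000 and 50).
#' @return A list with `spots` (data frame: `membrane_id`, `condition`,
#'   `row`, `col`, `intensity`) and `truth` (analyte-level planted fold
#'   changes and latent control values).
#' @export
generate_cytokine_membranes <- function(config, layout,
                                        pos_level = 1000, background = 50) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  layout <- validate_layout(layout)
  set.seed(config$seed)

  analytes <- unique(layout$name[layout$role == "analyte"])
  n <- length(analytes)
  # latent normalised control-condition values on the post-normalisation
  # scale of the scoring module (POS == 1), spanning faint to strong spots
  value_ctrl <- pmin(2, pmax(config$floor * 1.2,
                             exp(stats::rnorm(n, log(0.15), 1))))

  n_de <- round(config$de_fraction * n)
  is_de <- rep(FALSE, n)
  if (n_de > 0) is_de[sample.int(n, n_de)] <- TRUE
  mag <- stats::runif(n, config$effect_log2fc_range[1],
                      config$effect_log2fc_range[2])
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  true_log2fc <- ifelse(is_de, sgn * mag, 0)
  names(value_ctrl) <- names(true_log2fc) <- analytes

  k <- config$array_replicates_per_group
  membranes <- data.frame(
    membrane_id = c(paste0("control_", seq_len(k)),
                    paste0("treated_", seq_len(k))),
    condition = rep(c("control", "treated"), each = k)
  )

  spots <- do.call(rbind, lapply(seq_len(nrow(membranes)), function(i) {
    cond <- membranes$condition[i]
    value <- value_ctrl * (if (cond == "treated") 2^true_log2fc else 1)
    raw <- numeric(nrow(layout))
    for (j in seq_len(nrow(layout))) {
      raw[j] <- switch(layout$role[j],
        POS = pos_level,
        NEG = background,
        BLANK = background,
        analyte = {
          v <- value[[layout$name[j]]]
          noise <- if (config$noise_cv > 0) {
            stats::rnorm(1, 1, config$noise_cv)
          } else 1
          background + v * (pos_level - background) * max(noise, 0)
        })
    }
    data.frame(membrane_id = membranes$membrane_id[i], condition = cond,
               row = layout$row, col = layout$col, intensity = raw)
  }))
  rownames(spots) <- NULL

  truth <- data.frame(analyte = analytes, is_de = is_de,
                      true_log2fc = true_log2fc,
                      control_value = value_ctrl, row.names = NULL)
  list(spots = spots, truth = truth)
}
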