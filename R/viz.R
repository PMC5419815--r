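#' Colour rules for heat maps and score bars
#'
#' Three fixed semantics are used throughout the reports: indicator cells are
#' coloured by their severity level (low/medium = yellow, high = orange,
#' extreme = red, not available = blank); severity bars are yellow below 10,
#' orange in `[10, 20)` and red at 20 and above; need bars are yellow below
#' 50, orange in `[50, 150)` and red at 150 and above. All bins are half-open
#' with the boundary on the severer side, matching the boundary convention of
#' the classifier.
#'
#' @param scale `"indicator_level"`, `"severity_bins"` or `"need_bins"`.
#' @param colors Named vector of colour codes for `yellow`, `orange`, `red`;
#'   the defaults may be overridden.
#' @param missing_color Fill used for unavailable cells (`NA` = blank).
#' @return A list with class `cescore_color_rule`.
#' @export
color_rule <- function(scale = c("indicator_level", "severity_bins",
                                 "need_bins"),
                       colors = c(yellow = "#FFD700", orange = "#FF8C00",
                                  red = "#CC0000"),
                       missing_color = NA) {
  scale <- match.arg(scale)
  stopifnot(all(c("yellow", "orange", "red") %in% names(colors)))
  bins <- switch(scale,
    indicator_level = NULL,
    severity_bins = c(10, 20),
    need_bins = c(50, 150)
  )
  structure(list(scale = scale, bins = bins, colors = colors,
                 missing_color = missing_color),
            class = "cescore_color_rule")
}

#' Colour name for a severity level or a score
#'
#' `level_color()` maps severity levels to colour names; `score_color()` bins
#' a severity or need score. Both return the names `"yellow"`, `"orange"`,
#' `"red"` (or `NA` for unavailable levels) — use the rule's `colors` table to
#' resolve them to codes.
#'
#' @param level Character vector of severity levels (`NA` allowed).
#' @param score Numeric vector of resolved scores.
#' @param rule A [color_rule()] with binned scale (for `score_color`).
#' @return Character vector of colour names.
#' @examples
#' score_color(c(4, 15, 33), color_rule("severity_bins"))
#' score_color(c(25, 70, 216), color_rule("need_bins"))
#' @export
level_color <- function(level) {
  assert_level(level)
  c(low_medium = "yellow", high = "orange",
    extreme = "red")[level] |> unname()
}

#' @rdname level_color
#' @export
score_color <- function(score, rule) {
  stopifnot(inherits(rule, "cescore_color_rule"))
  if (is.null(rule$bins)) {
    rlang::abort("score_color needs a binned rule (severity_bins or need_bins)",
                 class = "cescore_config_error")
  }
  ifelse(score >= rule$bins[2], "red",
         ifelse(score >= rule$bins[1], "orange", "yellow"))
}

#' Heat map of indicator severity levels
#'
#' Draws the country-by-indicator grid: countries as rows, the four
#' vulnerability indicators then the four exposure indicators as columns, one
#' panel per assessment date. Cell colour comes from the already-classified
#' level in the scored record (never recomputed from raw values); cells whose
#' value was not available are left blank.
#'
#' @param scored A scored panel from [score_panel()].
#' @param config The model configuration (fixes the column order).
#' @param rule An `indicator_level` [color_rule()].
#' @param sort_by Optional column of `scored` to order countries by
#'   (descending); default alphabetical.
#' @return A ggplot object.
#' @export
render_heatmap <- function(scored, config = default_model_config(),
                           rule = color_rule("indicator_level"),
                           sort_by = NULL) {
  config <- validate_model_config(config)
  if (nrow(scored) == 0L) {
    rlang::abort("empty scored panel", class = "cescore_input_error")
  }
  lev_cols <- paste0("level_", config$name)
  miss <- setdiff(lev_cols, names(scored))
  if (length(miss) > 0L) {
    rlang::abort(paste0("scored panel lacks level column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "cescore_input_error")
  }
  long <- tidyr::pivot_longer(
    scored[, c("country", "assessment_date", lev_cols)],
    cols = dplyr::all_of(lev_cols),
    names_to = "indicator", values_to = "level",
    names_prefix = "level_"
  )
  long$indicator <- factor(long$indicator, levels = config$name)
  countries <- if (is.null(sort_by)) {
    sort(unique(long$country), decreasing = TRUE) # reversed so A is on top
  } else {
    ord <- scored[order(-scored[[sort_by]], scored$country), ]
    rev(unique(ord$country))
  }
  long$country <- factor(long$country, levels = countries)
  long$color <- level_color(long$level)

  fills <- rule$colors[c("yellow", "orange", "red")]
  names(fills) <- c("yellow", "orange", "red")

  ggplot2::ggplot(long, ggplot2::aes(x = .data$indicator, y = .data$country,
                                     fill = .data$color)) +
    ggplot2::geom_tile(color = "grey60", linewidth = 0.3) +
    ggplot2::scale_fill_manual(
      values = fills, na.value = rule$missing_color %||% NA,
      breaks = c("yellow", "orange", "red"),
      labels = c("low/medium", "high", "extreme"),
      name = "severity level"
    ) +
    ggplot2::facet_wrap(~assessment_date) +
    ggplot2::scale_x_discrete(position = "top") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 45, hjust = 0),
      panel.grid = ggplot2::element_blank()
    )
}

#' Standalone HTML table variant of the heat map
#'
#' @inheritParams render_heatmap
#' @param path Output `.html` path.
#' @return `path`, invisibly.
#' @export
heatmap_html <- function(scored, path, config = default_model_config(),
                         rule = color_rule("indicator_level")) {
  config <- validate_model_config(config)
  if (nrow(scored) == 0L) {
    rlang::abort("empty scored panel", class = "cescore_input_error")
  }
  lev_cols <- paste0("level_", config$name)
  scored <- scored[order(scored$assessment_date, scored$country), ]
  esc <- function(x) gsub("<", "&lt;", gsub("&", "&amp;", x))
  rows_html <- character(0)
  for (d in unique(scored$assessment_date)) {
    sub <- scored[scored$assessment_date == d, ]
    rows_html <- c(rows_html,
      paste0("<h2>", esc(d), "</h2>"),
      "<table border='1' cellspacing='0' cellpadding='4'>",
      paste0("<tr><th>country</th>",
             paste0("<th>", esc(config$name), "</th>", collapse = ""), "</tr>"))
    for (i in seq_len(nrow(sub))) {
      cells <- vapply(lev_cols, function(lc) {
        lev <- sub[[lc]][i]
        if (is.na(lev)) return("<td></td>") # unavailable: blank square
        paste0("<td style='background:",
               rule$colors[[level_color(lev)]], "'>&nbsp;</td>")
      }, character(1))
      rows_html <- c(rows_html,
        paste0("<tr><td>", esc(sub$country[i]), "</td>",
               paste(cells, collapse = ""), "</tr>"))
    }
    rows_html <- c(rows_html, "</table>")
  }
  html <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
            "<title>severity heat map</title></head><body>",
            rows_html, "</body></html>")
  writeLines(html, path)
  invisible(path)
}

#' Bar chart of severity or need scores
#'
#' One bar per country, height equal to the score, coloured by the standard
#' bins: severity below 10 yellow, 10 to just under 20 orange, 20 and above
#' red; need below 50 yellow, 50 to just under 150 orange, 150 and above red.
#' Countries whose score is unresolved are omitted with a notice.
#'
#' @param scored A scored panel from [score_panel()].
#' @param which `"severity"` or `"need"`.
#' @param rule A binned [color_rule()]; defaults to the matching scale.
#' @return A ggplot object.
#' @export
render_score_bars <- function(scored, which = c("severity", "need"),
                              rule = NULL) {
  which <- match.arg(which)
  col <- paste0(which, "_score")
  if (is.null(rule)) {
    rule <- color_rule(if (which == "severity") "severity_bins"
                       else "need_bins")
  }
  dat <- scored[, c("country", "assessment_date", col)]
  names(dat)[3] <- "score"
  unresolved <- dat$country[is.na(dat$score)]
  if (length(unresolved) > 0L) {
    message("omitting ", length(unresolved), " country(ies) with unresolved ",
            which, " score: ", paste(unresolved, collapse = ", "))
    dat <- dat[!is.na(dat$score), ]
  }
  if (nrow(dat) == 0L) {
    rlang::abort("no resolved scores to plot", class = "cescore_input_error")
  }
  dat$color <- score_color(dat$score, rule)
  fills <- rule$colors[c("yellow", "orange", "red")]

  ggplot2::ggplot(dat, ggplot2::aes(x = .data$country, y = .data$score,
                                    fill = .data$color)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = fills,
                               breaks = c("yellow", "orange", "red"),
                               name = paste(which, "bin")) +
    ggplot2::facet_wrap(~assessment_date) +
    ggplot2::labs(x = NULL, y = paste(which, "score")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Save a plot to PNG or SVG
#'
#' @param plot A ggplot object.
#' @param path Output path ending in `.png` or `.svg`.
#' @param width,height Size in inches.
#' @return `path`, invisibly.
#' @export
save_plot <- function(plot, path, width = 9, height = 6) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "svg")) {
    rlang::abort("output format must be png or svg",
                 class = "cescore_input_error")
  }
  if (ext == "svg") {
    grDevices::svg(path, width = width, height = height)
    print(plot)
    grDevices::dev.off()
  } else {
    ggplot2::ggsave(path, plot, width = width, height = height, dpi = 150)
  }
  invisible(path)
}
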