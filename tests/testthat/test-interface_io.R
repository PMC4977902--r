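test_that("the default preset carries the tool's normative settings", {
  p <- load_preset("default")
  expect_equal(p$x, 32L)
  expect_equal(p$y, 32L)
  expect_equal(p$mcs, 32L)
  expect_equal(p$substeps, 64L)
  expect_equal(p$max_sigma, 2L)
  expect_equal(p$matrix_density, 0.8)
  expect_equal(p$temperature, 10)
  expect_equal(p$j_ecm, 16)
  expect_equal(p$j_light, 15)
  expect_equal(p$j_dark, 2)
  expect_equal(p$j_mixed, 11)
  expect_equal(p$lam, 0.05)
  expect_equal(p$target_area_factor_light, 0.4)
  expect_equal(p$target_area_factor_dark, 0.4)
  expect_equal(p$dark_light_ratio, 0.25)
  expect_equal(p$target_growth_rate, 0)
})

test_that("literature presets validate and flag default-filled fields", {
  for (name in preset_names()) {
    p <- load_preset(name)
    expect_s3_class(p, "cpm_params")
    expect_identical(attr(p, "preset"), name)
  }
  ouchi <- load_preset("ouchi2003")
  expect_true("j_mixed" %in% attr(ouchi, "filled_defaults"))
  expect_error(load_preset("nope"), "default.*ggh1992")
})

test_that("config files override preset fields by flag-style keys", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("max-sigma: 4", "matrix-density: 0.5", "ratio: 1/2",
               "target-area-light: 0.3"), cfg)
  p <- read_config(cfg)
  expect_equal(p$max_sigma, 4L)
  expect_equal(p$matrix_density, 0.5)
  expect_equal(p$dark_light_ratio, 0.5)
  expect_equal(p$target_area_factor_light, 0.3)
  expect_equal(p$temperature, 10) # untouched default

  cfg_json <- tempfile(fileext = ".json")
  writeLines('{"temperature": 20, "seed": 7}', cfg_json)
  pj <- read_config(cfg_json)
  expect_equal(pj$temperature, 20)
  expect_equal(pj$seed, 7L)

  bad <- tempfile(fileext = ".yaml")
  writeLines("nonsense: 1", bad)
  expect_error(read_config(bad), "unknown config key")
})

test_that("trajectory CSV export round-trips every recorded count", {
  p <- sim_params(mcs = 5, max_sigma = 4, seed = 13)
  tr <- suppressWarnings(run_simulation(p))
  out <- tempfile(fileext = ".csv")
  export_csv(tr, out)
  lines <- readLines(out)
  expect_length(lines, 7L) # header + 6 steps
  expect_match(lines[1], "^\"?step\"?,")

  back <- read_trajectory_csv(out)
  orig <- as.data.frame(tr)
  expect_equal(back$sigma_1, orig$sigma_1)
  expect_equal(back$dark_total, orig$dark_total)
  expect_equal(back$light_total, orig$light_total)
  expect_equal(back$ecm_total, orig$ecm_total)
  expect_true(all(back$dark_total + back$light_total + back$ecm_total ==
                    p$x * p$y))

  # mcs = 0: header plus the single initialization row
  tr0 <- run_simulation(sim_params(mcs = 0, seed = 1))
  out0 <- tempfile(fileext = ".csv")
  export_csv(tr0, out0)
  expect_length(readLines(out0), 2L)
})

test_that("undefined ratios are written as empty CSV fields", {
  p <- sim_params(x = 4, y = 4, max_sigma = 1, matrix_density = 1,
                  mcs = 1, substeps = 16, seed = 1)
  tr <- run_simulation(p)
  out <- tempfile(fileext = ".csv")
  export_csv(tr, out)
  expect_match(readLines(out)[2], ",,", fixed = TRUE)
  expect_true(all(is.na(read_trajectory_csv(out)$dark_light_ratio)))
})

test_that("graph JSON has one node per site with palette colors", {
  p <- sim_params(x = 2, y = 2, matrix_density = 0, seed = 1)
  st <- initialize_lattice(p)
  out <- tempfile(fileext = ".json")
  export_graph_json(st, p, out)
  doc <- jsonlite::read_json(out)
  nodes <- doc$elements$nodes
  expect_length(nodes, 4L)
  expect_length(doc$elements$edges, 0L)
  expect_true(all(vapply(nodes, function(n) n$data$color, "") == "#BEBEBE"))
  expect_true(all(vapply(nodes, function(n) n$data$tau_class, "") == "ecm"))
  ids <- vapply(nodes, function(n) n$data$id, "")
  expect_length(unique(ids), 4L)
})

test_that("regrouping JSON nodes by spin reproduces every cell's area", {
  p <- sim_params(x = 8, y = 6, max_sigma = 4, seed = 17)
  st <- initialize_lattice(p)
  out <- tempfile(fileext = ".json")
  export_graph_json(st, p, out, edges = TRUE)
  doc <- jsonlite::read_json(out)
  sigma <- vapply(doc$elements$nodes, function(n) n$data$sigma, 0)
  counts <- table(factor(sigma, levels = 0:4))
  expect_equal(as.integer(counts[-1]), st$cells$area)
  expect_equal(as.integer(counts[1]), cell_area(st, 0))
  # dark cells get red/purple tones, light cells blue/green tones
  pal <- cpm_palette(4)
  expect_equal(unname(pal["0"]), "#BEBEBE")
  expect_false(any(duplicated(pal)))
})

test_that("snapshot rendering is deterministic and color-faithful", {
  p <- sim_params(x = 8, y = 6, max_sigma = 2, seed = 19)
  st <- initialize_lattice(p)
  f1 <- tempfile(fileext = ".png")
  f2 <- tempfile(fileext = ".png")
  render_snapshot(st, p, f1, scale = 2)
  render_snapshot(st, p, f2, scale = 2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  img <- png::readPNG(f1)
  hex <- grDevices::rgb(img[, , 1], img[, , 2], img[, , 3])
  pal <- cpm_palette(2)
  counts <- table(factor(toupper(hex), levels = unname(pal)))
  expect_equal(as.integer(counts) / 4L, # 2x2 pixel block per site
               c(cell_area(st, 0), st$cells$area))

  # all-ECM lattice renders a single grey image
  p0 <- sim_params(x = 3, y = 3, matrix_density = 0, seed = 1)
  f0 <- tempfile(fileext = ".png")
  render_snapshot(initialize_lattice(p0), p0, f0, scale = 1)
  img0 <- png::readPNG(f0)
  expect_length(unique(grDevices::rgb(img0[, , 1], img0[, , 2],
                                      img0[, , 3])), 1L)
})

test_that("the CLI runs, writes outputs and reports validation failures", {
  csv <- tempfile(fileext = ".csv")
  out <- capture.output(
    status <- cpm_cli(c("run", "--preset", "default", "--seed", "1",
                        "--out-csv", csv)))
  expect_equal(status, 0L)
  expect_length(readLines(csv), 34L) # header + 33 recorded steps

  expect_message(
    status_bad <- cpm_cli(c("run", "--matrix-density", "1.5")),
    "matrix_density")
  expect_equal(status_bad, 1L)

  expect_message(status_flag <- cpm_cli(c("run", "--bogus", "1")),
                 "unknown flag")
  expect_equal(status_flag, 1L)

  listing <- capture.output(status_p <- cpm_cli("presets"))
  expect_equal(status_p, 0L)
  for (name in preset_names()) expect_match(listing, name, all = FALSE)
})

test_that("CLI init and sweep write the requested artifacts", {
  json <- tempfile(fileext = ".json")
  png_file <- tempfile(fileext = ".png")
  out <- capture.output(
    status <- cpm_cli(c("init", "--x", "6", "--y", "6", "--seed", "2",
                        "--out-json", json, "--out-png", png_file)))
  expect_equal(status, 0L)
  expect_length(jsonlite::read_json(json)$elements$nodes, 36L)
  expect_true(file.size(png_file) > 0)

  dir <- tempfile("sweep")
  out <- capture.output(
    status <- cpm_cli(c("sweep", "--param", "temperature",
                        "--values", "0,20", "--seeds", "1:2",
                        "--x", "8", "--y", "8", "--mcs", "2",
                        "--substeps", "32", "--out-dir", dir)))
  expect_equal(status, 0L)
  summary <- utils::read.csv(file.path(dir, "summary.csv"))
  expect_equal(nrow(summary), 4L)
  expect_setequal(summary$value, c(0, 20))
  expect_true(all(file.exists(file.path(dir, summary$file))))
})
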