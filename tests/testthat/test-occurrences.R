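test_that("records with missing coordinates are dropped and counted", {
  tab <- data.frame(species = c("a", "a", "b"),
                    latitude = c(1, 2, 3),
                    longitude = c(10, NA, 30))
  expect_message(occ <- read_occurrences(tab), "1 record")
  expect_equal(nrow(occ), 2L)
  expect_equal(attr(occ, "n_dropped"), 1L)
  expect_equal(occ$species_id, c("a", "b"))

  # unparseable text coordinates count as missing too
  tab2 <- data.frame(species = "a", latitude = "not-a-number",
                     longitude = "5", stringsAsFactors = FALSE)
  expect_error(suppressMessages(read_occurrences(tab2)), "no occurrence")

  # all rows parseable: identity, in input order
  tab3 <- data.frame(species = c("b", "a"), latitude = c(2, 1),
                     longitude = c(20, 10))
  occ3 <- read_occurrences(tab3)
  expect_equal(nrow(occ3), nrow(tab3))
  expect_equal(attr(occ3, "n_dropped"), 0L)
  expect_equal(occ3$species_id, c("b", "a"))
})

test_that("column configuration and range checks behave as declared", {
  tab <- data.frame(taxon = "a", y = 91, x = 5)
  expect_error(read_occurrences(tab), "required column")
  expect_warning(read_occurrences(tab, species_col = "taxon",
                                  lat_col = "y", lon_col = "x"),
                 "WGS84")
  occ <- suppressWarnings(read_occurrences(tab, species_col = "taxon",
                                           lat_col = "y", lon_col = "x"))
  expect_equal(nrow(occ), 1L)
  expect_error(read_occurrences(tab, species_col = "taxon", lat_col = "y",
                                lon_col = "x", range_check = "error"),
               "WGS84")
  expect_silent(read_occurrences(tab, species_col = "taxon",
                                 lat_col = "y", lon_col = "x",
                                 range_check = "ignore"))
})

test_that("per-species class tallies count only classified points", {
  r <- label_raster(rbind(c("Af", "Bf"), c(NA, "Bf")))
  # 5 points of one species inside the single Af cell
  occ <- occ_df(rep("sp1", 5), runif(5, 1.01, 1.99), runif(5, 0.01, 0.99))
  tal <- tally_classes(occ, r)
  expect_equal(unclass(tal)["sp1", "Af"], 5L)
  expect_equal(sum(unclass(tal)["sp1", ]), 5L)

  # two patches, 4 points each
  occ2 <- rbind(occ_df(rep("sp2", 4), runif(4, 1.01, 1.99),
                       runif(4, 0.01, 0.99)),
                occ_df(rep("sp2", 4), runif(4, 0.01, 1.99),
                       runif(4, 1.01, 1.99)))
  tal2 <- tally_classes(occ2, r)
  expect_equal(unname(unclass(tal2)["sp2", c("Af", "Bf")]), c(4L, 4L))

  # all points in nodata -> empty counts, tracked in metadata
  occ3 <- occ_df(rep("sp3", 3), runif(3, 0.01, 0.99), runif(3, 0.01, 0.99))
  tal3 <- tally_classes(occ3, r)
  expect_equal(sum(unclass(tal3)["sp3", ]), 0L)
  expect_equal(unname(attr(tal3, "n_nodata")["sp3"]), 3L)
})

test_that("minimum-occurrence filter removes classes at or below threshold", {
  r <- label_raster(rbind(c("Af", "Aw")))
  occ <- rbind(occ_df(rep("s", 4), runif(4, 0.01, 0.99), runif(4, 0.01, 0.99)),
               occ_df(rep("s", 3), runif(3, 0.01, 0.99), runif(3, 1.01, 1.99)))
  tal <- tally_classes(occ, r)
  f <- filter_min_occurrences(tal, 3L)
  expect_equal(unname(unclass(f)["s", c("Af", "Aw")]), c(4L, 0L))

  # all classes at or below threshold -> everything removed
  f2 <- filter_min_occurrences(tal, 4L)
  expect_equal(sum(unclass(f2)), 0L)

  # threshold 0 keeps every observed class
  f0 <- filter_min_occurrences(tal, 0L)
  expect_identical(unname(unclass(f0)["s", ]), unname(unclass(tal)["s", ]))
})

test_that("niche breadth is retained-class cardinality, zeros kept", {
  r <- label_raster(rbind(c("Af", "Aw"), c("Cfb", "Cfb")))
  occ <- rbind(
    occ_df(rep("wide", 4), runif(4, 1.01, 1.99), runif(4, 0.01, 0.99)),
    occ_df(rep("wide", 5), runif(5, 1.01, 1.99), runif(5, 1.01, 1.99)),
    occ_df(rep("wide", 6), runif(6, 0.01, 0.99), runif(6, 0.01, 1.99)),
    occ_df(rep("narrow", 2), runif(2, 1.01, 1.99), runif(2, 0.01, 0.99)))
  b <- compute_breadth(occ, r)
  expect_equal(b$B_s[b$species_id == "wide"], 3L)
  expect_equal(b$retained_classes[b$species_id == "wide"], "Af;Aw;Cfb")
  expect_equal(b$B_s[b$species_id == "narrow"], 0L)
  expect_equal(b$n_points[b$species_id == "wide"], 15L)
})

test_that("breadth is monotone in points and antitone in the threshold", {
  r <- label_raster(rbind(c("Af", "Aw"), c("Cfb", "Dfb")))
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    occ <- occ_df(rep("s", n), runif(n, 0.01, 1.99), runif(n, 0.01, 1.99))
    b1 <- compute_breadth(occ, r)$B_s
    # adding points never decreases breadth
    extra <- occ_df(rep("s", 5), runif(5, 0.01, 1.99), runif(5, 0.01, 1.99))
    b2 <- compute_breadth(rbind(occ, extra), r)$B_s
    expect_gte(b2, b1)
    # raising the threshold never increases breadth
    for (thr in 0:5) {
      bt <- niche_breadth(filter_min_occurrences(tally_classes(occ, r), thr))
      if (thr > 0) expect_lte(bt$B_s, prev)
      prev <- bt$B_s
    }
    # duplicating a point of an already-retained class leaves breadth fixed
    tal <- filter_min_occurrences(tally_classes(occ, r), 3L)
    kept <- colnames(tal)[unclass(tal)["s", ] > 0]
    if (length(kept) > 0) {
      dup <- occ[lookup_class(r, occ$longitude, occ$latitude) %in% kept, ][1, ]
      b3 <- compute_breadth(rbind(occ, dup), r)$B_s
      expect_equal(b3, b1)
    }
    expect_lte(b1, nrow(r$legend))
  }
})

test_that("pooled retained classes equal a naive nested-loop recount", {
  set.seed(7)
  r <- make_raster(5, nrow = 15, ncol = 15, margin = 1, seed = 8)
  n <- 300
  occ <- occ_df(sample(paste0("sp", 1:6), n, replace = TRUE),
                runif(n, 0, 7.5), runif(n, 0, 7.5))
  b <- compute_breadth(occ, r, threshold = 3L)
  pooled <- sort(unique(unlist(strsplit(b$retained_classes, ";"))))

  # brute force: loop over species and classes with explicit counting
  naive <- character(0)
  for (sp in unique(occ$species_id)) {
    rows <- occ[occ$species_id == sp, ]
    labs <- lookup_class(r, rows$longitude, rows$latitude)
    for (cl in unique(labs[!is.na(labs)])) {
      cnt <- 0
      for (i in seq_along(labs)) {
        if (!is.na(labs[i]) && labs[i] == cl) cnt <- cnt + 1
      }
      if (cnt > 3) naive <- union(naive, cl)
    }
  }
  expect_equal(pooled, sort(naive))
})
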