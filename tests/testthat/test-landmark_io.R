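# Reading, writing and decoding the landmark and metadata formats.

test_that("TPS records are parsed, scaled and round-tripped losslessly", {
  tf <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=3", "0 0", "1 0", "0 1", "ID=t1",
               "LM=3", "2 2", "3 2", "2 4", "IMAGE=img2.jpg", "SCALE=0.5"),
             tf)
  d <- read_tps(tf)
  expect_equal(d$n, 2L)
  expect_equal(d$k, 3L)
  expect_equal(d$m, 2L)
  expect_equal(d$ids[1], "t1")
  expect_equal(d$coords[, , 1], matrix(c(0, 0, 1, 0, 0, 1), 3, 2,
                                       byrow = TRUE))
  # SCALE= applied multiplicatively; id falls back to IMAGE=
  expect_equal(d$coords[, , 2], 0.5 * matrix(c(2, 2, 3, 2, 2, 4), 3, 2,
                                             byrow = TRUE))
  expect_equal(d$ids[2], "img2.jpg")

  # round trip on a generated 12-landmark file preserves every value
  cfg <- simulation_config(k = 12, m = 2, seed = 3)
  gen <- generate_dataset(cfg)
  tf2 <- withr::local_tempfile(fileext = ".tps")
  write_tps(gen, tf2)
  back <- read_tps(tf2)
  expect_identical(back$coords, gen$coords)
  expect_identical(back$ids, gen$ids)
})

test_that("malformed and empty TPS files are handled", {
  tf <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=3", "0 0", "1 0", "ID=bad"), tf)
  expect_error(read_tps(tf), "record 1")
  writeLines(character(0), tf)
  expect_equal(read_tps(tf)$n, 0L)
})

test_that("wide landmark tables round-trip with metadata decoded", {
  cfg <- simulation_config(k = 9, m = 3, seed = 4,
                           groups = data.frame(label = c("H", "Z"),
                                               n = c(3L, 2L),
                                               offset = c(0.02, 0.02)))
  gen <- generate_dataset(cfg)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_landmark_table(gen, tf)
  back <- read_landmark_table(tf, dims = 3)
  expect_equal(back$k, 9L)
  expect_equal(back$n, 5L)
  expect_equal(back$coords, gen$coords, tolerance = 1e-12)
  expect_equal(back$meta$group, gen$meta$group)
  # group decoded from the ID string
  expect_true(all(back$meta$group_label[back$meta$group == "Z"] == "zebra"))
})

test_that("rows with wrong coordinate counts name the specimen", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID_String,a,b,c,d,e,f",
               "B_1_H_arb_F,0,0,1,0,0,1",
               "B_2_H_arb_F,0,0,1,0,0,oops"), tf)
  expect_error(read_landmark_table(tf, dims = 2), "B_2_H_arb_F")
})

test_that("ID strings decode against the full legend and reject bad codes", {
  md <- parse_id_string("B_123_H_arb_F")
  expect_equal(md$museum, "B")
  expect_equal(md$group_label, "horse")
  expect_equal(md$breed_label, "Arab")
  expect_equal(md$morphotype_label, "Light horse")

  md2 <- parse_id_string("V_9_D_aaa_A")
  expect_equal(md2$group, "D")
  expect_equal(md2$breed_label, "not a domesticated horse")
  expect_equal(md2$morphotype_label, "not a domesticated horse")

  expect_error(parse_id_string("X_1_H_arb_F"), "valid codes")
  expect_error(parse_id_string("B_1_Q_aaa_A"), "valid codes")
  # consistency rules: breed iff horse, morphotype A iff non-horse
  expect_error(parse_id_string("B_1_D_arb_A"), "breed")
  expect_error(parse_id_string("B_1_H_arb_A"), "morphotype")

  # the decoding is a bijection over every legend table
  tabs <- id_code_tables()
  expect_false(anyDuplicated(names(tabs$breed)) > 0)
  expect_false(anyDuplicated(tabs$breed) > 0)
  expect_equal(length(tabs$breed), 39L)
  for (b in setdiff(names(tabs$breed), "aaa")) {
    md <- parse_id_string(paste("K", "7", "H", b, "P", sep = "_"))
    expect_equal(md$breed_label, unname(tabs$breed[b]))
  }
  for (mus in names(tabs$museum))
    expect_equal(parse_id_string(paste(mus, "1", "Z", "aaa", "A",
                                       sep = "_"))$museum_label,
                 unname(tabs$museum[mus]))
})

test_that("shetland pony code decodes as in the collection legend", {
  expect_equal(parse_id_string("H_55_H_she_P")$breed_label, "Shetland Pony")
})
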