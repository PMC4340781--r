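test_that("registration and listing preserve order and reject duplicates", {
  reg <- new_registry()
  expect_identical(get_ds_list(reg), character())

  register_source(reg, data_source_entry("EBI", "web_service"))
  register_source(reg, data_source_entry("FTP-mock", "ftp"))
  expect_identical(get_ds_list(reg), c("EBI", "FTP-mock"))

  expect_error(register_source(reg, data_source_entry("EBI", "xml")),
               class = "mb_conflict_error")

  expect_error(data_source_entry("x", "carrier-pigeon"),
               class = "mb_argument_error")
})

test_that("listing scales to hundreds of sources without duplication", {
  reg <- new_registry()
  for (i in 1:200) register_source(reg, data_source_entry(sprintf("src%03d", i), "xml"))
  lst <- get_ds_list(reg)
  expect_length(lst, 200)
  expect_false(anyDuplicated(lst) > 0)
  expect_identical(lst[1], "src001")
  expect_identical(lst[200], "src200")
})

test_that("registration is atomic: a failing registration leaves no trace", {
  reg <- new_registry()
  expect_error(
    register_source(
      reg, data_source_entry("broken", "web_service"),
      elements = list(data_element("Thing", user_operations = "Poke")),
      operations = list(user_operation("Poke", "broken", "Thing", "simple",
                                       "no-such-generic-op"))),
    class = "mb_validation_error")
  expect_identical(get_ds_list(reg), character())
  expect_error(get_ds_metadata(reg, "broken"), class = "mb_not_found_error")
})

test_that("metadata round-trips exactly what was registered", {
  mocks <- make_mock_sources(seed = 3)
  md <- get_ds_metadata(mocks$registry, "FTP-mock")
  els <- vapply(md$elements, `[[`, "", "element_name")
  expect_setequal(els, c("File", "Directory"))
  ops <- unlist(lapply(md$elements, `[[`, "user_operations"))
  expect_setequal(ops, c("Read", "Write", "Delete", "Up_Navigation", "Down_Navigation"))
  file_el <- md$elements[[which(els == "File")]]
  expect_setequal(vapply(file_el$attributes, `[[`, "", "name"),
                  c("name", "size", "date", "type", "userID", "groupID",
                    "permissions", "numberofLinks"))
  expect_error(get_ds_metadata(mocks$registry, "nonexistent"),
               class = "mb_not_found_error")
})

test_that("operation lookup routes complex vs simple and is deterministic", {
  mocks <- make_mock_sources(seed = 3)
  r1 <- lookup_state_machine_model(mocks$registry, "FetchData", "EBI", "Protein")
  expect_identical(r1, list(kind = "complex", target = "FetchData.xml"))
  r2 <- lookup_state_machine_model(mocks$registry, "Read", "FTP-mock", "File")
  expect_identical(r2$kind, "simple")
  expect_identical(r2$target, "ftp.read")
  # pure function of registry state: repeated calls agree
  expect_identical(r1, lookup_state_machine_model(mocks$registry, "FetchData",
                                                  "EBI", "Protein"))
  expect_error(lookup_state_machine_model(new_registry(), "FetchData", "EBI", "Protein"),
               class = "mb_not_found_error")
})

test_that("mapping resolution answers with registered mappings only", {
  mocks <- make_mock_sources(seed = 3)
  m <- resolve_mapping(mocks$registry, "Access-read", "EBI")
  expect_identical(m$callable$method_name, "fetchData")
  expect_length(m$callable$parameter_specs, 3)
  expect_true(all(vapply(m$callable$parameter_specs, `[[`, "", "type") == "string"))
  # alias resolves to the same mapping
  expect_identical(resolve_mapping(mocks$registry, "Access-Read", "EBI")$result_key,
                   m$result_key)
  expect_error(resolve_mapping(mocks$registry, "Access-read", "no-such-source"),
               class = "mb_not_found_error")
  # every resolvable mapping is one that was registered
  for (src in get_ds_list(mocks$registry)) {
    maps <- mocks$registry$sources[[src]]$mappings
    for (key in names(maps)) {
      expect_identical(resolve_mapping(mocks$registry, key, src)$source_name, src)
    }
  }
})

test_that("registry serialization is canonical and byte-stable", {
  mocks <- make_mock_sources(seed = 5)
  j1 <- registry_to_json(mocks$registry)
  reg2 <- registry_from_json(j1)
  j2 <- registry_to_json(reg2)
  expect_identical(j1, j2)
  # reload preserves routing behaviour
  expect_identical(
    lookup_state_machine_model(reg2, "FetchData", "EBI", "Protein"),
    lookup_state_machine_model(mocks$registry, "FetchData", "EBI", "Protein"))
  expect_identical(get_ds_list(reg2), get_ds_list(mocks$registry))
})

test_that("exact element registrations beat wildcard ones", {
  reg <- new_registry()
  register_source(
    reg, data_source_entry("s", "web_service"),
    elements = list(data_element("Gene", user_operations = "FetchData"),
                    data_element("Protein", user_operations = "FetchData")),
    mappings = list(
      api_mapping("generic.fetch", "s",
                  callable_descriptor("t", "f"), result_key = "r"),
      api_mapping("gene.fetch", "s",
                  callable_descriptor("t", "g"), result_key = "r2")),
    operations = list(
      user_operation("FetchData", "s", "*", "simple", "generic.fetch"),
      user_operation("FetchData", "s", "Gene", "simple", "gene.fetch")))
  expect_identical(lookup_state_machine_model(reg, "FetchData", "s", "Gene")$target,
                   "gene.fetch")
  expect_identical(lookup_state_machine_model(reg, "FetchData", "s", "Protein")$target,
                   "generic.fetch")
  # equal-specificity duplicates fail at registration time
  expect_error(
    register_source(
      reg, data_source_entry("s2", "web_service"),
      elements = list(data_element("Gene", user_operations = "FetchData")),
      mappings = list(api_mapping("m", "s2", callable_descriptor("t", "f"),
                                  result_key = "r")),
      operations = list(
        user_operation("FetchData", "s2", "Gene", "simple", "m"),
        user_operation("FetchData", "s2", "Gene", "simple", "m"))),
    class = "mb_conflict_error")
})
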