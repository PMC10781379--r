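# Event packets, device identity, discovery and loopback delivery.

test_that("device id combines the common name and last four MAC digits", {
  expect_equal(make_device_id("E", "00:11:22:33:12:34")$id, "E-1234")
  expect_equal(make_device_id("E", "00:11:22:33:ab:cd")$id, "E-ABCD")
  # separator and case variants give the identical id
  variants <- c("00:11:22:33:12:34", "00-11-22-33-12-34", "001122331234",
                "00:11:22:33:12:34")
  ids <- vapply(variants, function(m) make_device_id("E", m)$id, character(1))
  expect_true(all(ids == "E-1234"))
  expect_error(make_device_id("E", "00:11:22:33:12"), "malformed")
  expect_error(make_device_id("E", "zz:11:22:33:12:34"), "malformed")
})

test_that("the fever rule is strict at the threshold", {
  id <- make_device_id("E", "001122331234")
  expect_null(build_thermal_event(id, 38.0, time = 1L))
  pkt <- build_thermal_event(id, 38.1, time = 1L)
  expect_s3_class(pkt, "event_packet")
  expect_equal(pkt$type, "thermal")
  expect_equal(pkt$temperature, 38.1)
  expect_error(build_thermal_event(id, NaN), "finite")
})

test_that("serialized packets match the golden byte-exact layout", {
  id <- make_device_id("E", "001122331234")
  pkt <- build_thermal_event(id, 38.5, time = 1700000000L)
  expect_identical(
    packet_json(pkt),
    "{\"id\":\"E-1234\",\"time\":1700000000,\"type\":\"thermal\",\"temperature\":38.5}"
  )
  expect_true(validate_packet_json(packet_json(pkt)))
  # schema file and serializer agree on the key vocabulary
  schema <- jsonlite::fromJSON(system.file("schema",
                                           "event-packet.schema.json",
                                           package = "feverwatch"))
  expect_true(all(names(unclass(pkt)) %in% names(schema$properties)))
})

test_that("cough packets embed the WAV bytes recoverably", {
  id <- make_device_id("E", "001122331234")
  clip <- synth_clip("cough", 3)
  pkt <- build_cough_event(id, clip, time = 1700000001L)
  expect_identical(sort(names(unclass(pkt))),
                   sort(c("id", "time", "type", "audio")))
  # base64 length: canonical 44-byte header + 2 bytes per sample
  expect_equal(nchar(pkt$audio), 4 * ceiling((44 + 32000) / 3))
  expect_identical(jsonlite::base64_dec(pkt$audio),
                   wav_bytes(clip$samples, clip$rate))
  # decoded bytes parse back to the same waveform
  back <- read_wav(jsonlite::base64_dec(pkt$audio))
  expect_identical(as.numeric(back$samples[, 1]), clip$samples)
  long <- audio_clip(numeric(16000 * 10))
  expect_error(build_cough_event(id, long, max_bytes = 1000L), "cap")
})

test_that("parsing inverts serialization on packet content", {
  id <- make_device_id("E", "001122331234")
  for (pkt in list(build_thermal_event(id, 39, time = 5L),
                   build_cough_event(id, synth_clip("cough", 1), time = 6L))) {
    expect_identical(unclass(parse_packet(packet_json(pkt))), unclass(pkt))
  }
  expect_error(parse_packet("{\"id\":\"x\",\"time\":1,\"type\":\"nope\"}"),
               "thermal")
  bad <- "{\"id\":\"x\",\"time\":1,\"type\":\"thermal\",\"audio\":\"AA==\"}"
  expect_error(parse_packet(bad), "temperature")
})

test_that("UDP discovery resolves the announcing mock server on loopback", {
  library(parallel)
  tcp <- free_port()
  udp <- free_port()
  job <- mcparallel(run_mock_server(tcp, udp, max_packets = 2, timeout = 30))
  ep <- discover_server(udp, timeout = 15)
  expect_s3_class(ep, "server_endpoint")
  expect_equal(ep$ip, "127.0.0.1")
  expect_equal(ep$port, tcp)
  id <- make_device_id("E", "001122331234")
  con <- telemetry_connect(ep)
  p1 <- build_thermal_event(id, 38.4, time = 10L)
  expect_equal(send_event(con, p1), "E-1234")
  p2 <- build_cough_event(id, synth_clip("cough", 2), time = 11L)
  send_event(con, p2)
  close(con)
  got <- mccollect(job)[[1]]
  expect_length(got, 2)
  expect_identical(unclass(got[[1]]), unclass(p1))
  expect_identical(unclass(got[[2]]), unclass(p2))
})

test_that("malformed announcements are ignored and timeouts error cleanly", {
  library(parallel)
  udp <- free_port()
  # garbage datagrams followed by a valid announcement, sent once the
  # listener is up
  job <- mcparallel({
    Sys.sleep(0.4)
    fd <- feverwatch:::.udp_open(0L)
    feverwatch:::.udp_send_to(fd, "127.0.0.1", udp, "not json")
    feverwatch:::.udp_send_to(fd, "127.0.0.1", udp,
                              "{\"service\":\"other\",\"x\":1}")
    feverwatch:::.udp_send_to(
      fd, "127.0.0.1", udp,
      "{\"service\":\"feverwatch\",\"ip\":\"127.0.0.1\",\"port\":9100}")
    feverwatch:::.udp_close(fd)
    TRUE
  })
  ep <- discover_server(udp, timeout = 10)
  mccollect(job)
  expect_equal(ep$port, 9100L)

  expect_error(discover_server(free_port(), timeout = 0.3),
               class = "feverwatch_no_server_error")
})

test_that("a dead server raises a retriable transport error, not a crash", {
  ep <- server_endpoint("127.0.0.1", free_port())
  expect_error(send_event(ep, build_thermal_event(
    make_device_id("E", "001122331234"), 39, time = 1L)),
    class = "feverwatch_transport_error")
  expect_error(server_endpoint("localhost", 80), "IPv4")
  expect_error(server_endpoint("127.0.0.1", 0), "port")
})
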