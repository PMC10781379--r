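# Event telemetry: JSON packets (thermal above-threshold rule, cough with
# base64-embedded WAV audio), device identity derived from the MAC address,
# UDP server auto-discovery, newline-delimited JSON over TCP, and a mock
# server for loopback interoperability tests.

b64encode <- function(bytes) gsub("\n", "", jsonlite::base64_enc(bytes),
                                  fixed = TRUE)
b64decode <- function(txt) jsonlite::base64_dec(txt)

#' Device identity from a common name and MAC address
#'
#' The device id is the common name joined with the last four hex digits of
#' the MAC address, uppercase, e.g. `"E-1234"`. Separator style (`:`/`-`/
#' none) and input case do not affect the id.
#'
#' @param common_name Short device name.
#' @param mac 6-byte MAC address string.
#' @return An object of class `device_identity` with `common_name`, `mac`
#'   (normalized), `id`.
#' @export
#' @examples
#' make_device_id("E", "aa:bb:cc:dd:12:34")$id  # "E-1234"
make_device_id <- function(common_name, mac) {
  hex <- toupper(gsub("[:.\\s-]", "", mac, perl = TRUE))
  if (!grepl("^[0-9A-F]{12}$", hex)) {
    stopf("malformed MAC address '%s'", mac)
  }
  structure(
    list(common_name = common_name,
         mac = paste(substring(hex, seq(1, 11, 2), seq(2, 12, 2)),
                     collapse = ":"),
         id = paste0(common_name, "-", substring(hex, 9, 12))),
    class = "device_identity"
  )
}

new_event_packet <- function(id, time, type, payload) {
  structure(c(list(id = id, time = as.integer(time), type = type), payload),
            class = "event_packet")
}

#' Thermal event packet (fever rule)
#'
#' A thermal packet is emitted only when the corrected patient temperature
#' is strictly above the threshold (default 38.0 degC); at or below it the
#' function returns `NULL`.
#'
#' @param identity A [make_device_id()] identity.
#' @param reading A `patient_reading` (or a plain corrected temperature).
#' @param threshold Fever threshold (degC).
#' @param time Event epoch time (integer seconds); defaults to now.
#' @return An `event_packet` or `NULL`.
#' @export
build_thermal_event <- function(identity, reading, threshold = 38.0,
                                time = as.integer(Sys.time())) {
  temp <- if (inherits(reading, "patient_reading")) reading$corrected
          else as.numeric(reading)
  if (!is.finite(temp)) stopf("corrected temperature is not finite")
  if (!(temp > threshold)) return(NULL)
  new_event_packet(identity$id, time, "thermal", list(temperature = temp))
}

#' Cough event packet with embedded audio
#'
#' The `audio` field carries the clip's complete WAV bytes, base64-encoded;
#' decoding recovers the WAV file bit-exactly.
#'
#' @param identity A [make_device_id()] identity.
#' @param clip An `audio_clip`.
#' @param time Event epoch time (integer seconds); defaults to now.
#' @param max_bytes Packet-size cap on the encoded WAV.
#' @return An `event_packet`.
#' @export
build_cough_event <- function(identity, clip,
                              time = as.integer(Sys.time()),
                              max_bytes = 262144L) {
  bytes <- wav_bytes(clip$samples, clip$rate)
  if (length(bytes) > max_bytes) {
    stopf("clip WAV (%d bytes) exceeds the packet cap (%d bytes)",
          length(bytes), max_bytes)
  }
  new_event_packet(identity$id, time, "cough", list(audio = b64encode(bytes)))
}

#' Serialize an event packet to its canonical JSON line
#'
#' Fixed key order (`id`, `time`, `type`, then the payload field), all keys
#' lowercase, full-precision numbers, no trailing newline.
#'
#' @param packet An `event_packet`.
#' @return A single-element character vector of JSON.
#' @export
packet_json <- function(packet) {
  as.character(jsonlite::toJSON(unclass(packet), auto_unbox = TRUE,
                                digits = NA))
}

#' Parse and validate a JSON event packet
#'
#' @param txt A JSON string as produced by [packet_json()].
#' @return An `event_packet`.
#' @export
parse_packet <- function(txt) {
  obj <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  validate_packet_fields(obj)
  payload <- if (obj$type == "thermal") {
    list(temperature = as.numeric(obj$temperature))  # "39" parses as int
  } else {
    list(audio = obj$audio)
  }
  new_event_packet(obj$id, obj$time, obj$type, payload)
}

validate_packet_fields <- function(obj) {
  if (is.null(obj$id) || !is.character(obj$id)) stopf("packet missing id")
  if (is.null(obj$time) || obj$time < 0) stopf("packet time invalid")
  if (is.null(obj$type) || !obj$type %in% c("thermal", "cough")) {
    stopf("packet type must be 'thermal' or 'cough'")
  }
  has_temp <- !is.null(obj$temperature)
  has_audio <- !is.null(obj$audio)
  if (obj$type == "thermal" && !(has_temp && !has_audio)) {
    stopf("thermal packet must carry exactly the temperature payload")
  }
  if (obj$type == "cough" && !(has_audio && !has_temp)) {
    stopf("cough packet must carry exactly the audio payload")
  }
  invisible(TRUE)
}

#' Validate a serialized packet against the bundled schema conventions
#'
#' Checks the key set, key order, and payload rule of the packet schema
#' shipped at `inst/schema/event-packet.schema.json`.
#'
#' @param txt JSON string.
#' @return `TRUE` (invisibly) or an error.
#' @export
validate_packet_json <- function(txt) {
  obj <- jsonlite::fromJSON(txt)
  validate_packet_fields(obj)
  expected <- c("id", "time", "type",
                if (obj$type == "thermal") "temperature" else "audio")
  if (!identical(names(obj), expected)) {
    stopf("packet keys must be exactly [%s] in order",
          paste(expected, collapse = ", "))
  }
  invisible(TRUE)
}

#' Server endpoint record
#'
#' @param ip Dotted-quad IPv4 address.
#' @param port TCP port (1-65535).
#' @param discovered_at Epoch seconds of discovery.
#' @return An object of class `server_endpoint`.
#' @export
server_endpoint <- function(ip, port, discovered_at = as.integer(Sys.time())) {
  if (!grepl("^([0-9]{1,3}\\.){3}[0-9]{1,3}$", ip)) {
    stopf("invalid IPv4 address '%s'", ip)
  }
  port <- as.integer(port)
  if (is.na(port) || port < 1 || port > 65535) stopf("invalid port")
  structure(list(ip = ip, port = port, discovered_at = discovered_at),
            class = "server_endpoint")
}

ANNOUNCE_SERVICE <- "feverwatch"

announcement_json <- function(ip, tcp_port) {
  as.character(jsonlite::toJSON(
    list(service = ANNOUNCE_SERVICE, ip = ip, port = as.integer(tcp_port)),
    auto_unbox = TRUE))
}

#' Discover the telemetry server via UDP announcements
#'
#' Listens on the announcement port until a valid announcement
#' (`{"service":"feverwatch","ip":...,"port":...}`) arrives; malformed
#' datagrams are ignored and discovery continues. The first valid
#' announcement wins.
#'
#' @param udp_port Announcement port (default 5005).
#' @param timeout Seconds to wait before failing.
#' @return A [server_endpoint()].
#' @export
discover_server <- function(udp_port = 5005L, timeout = 5) {
  fd <- .udp_open(as.integer(udp_port))
  on.exit(.udp_close(fd))
  deadline <- Sys.time() + timeout
  repeat {
    remaining <- as.numeric(difftime(deadline, Sys.time(), units = "secs"))
    if (remaining <= 0) {
      stop(errorCondition(
        sprintf("no server announcement on UDP port %d within %.1f s",
                udp_port, timeout),
        class = c("feverwatch_no_server_error", "feverwatch_transport_error")))
    }
    msg <- .udp_recv_from(fd, as.integer(remaining * 1000))
    if (is.null(msg)) next
    ann <- tryCatch(jsonlite::fromJSON(msg$payload), error = function(e) NULL)
    if (is.null(ann) || !identical(ann$service, ANNOUNCE_SERVICE) ||
        is.null(ann$ip) || is.null(ann$port)) {
      next  # malformed or foreign announcement: keep listening
    }
    ep <- tryCatch(server_endpoint(ann$ip, ann$port), error = function(e) NULL)
    if (!is.null(ep)) return(ep)
  }
}

transport_error <- function(fmt, ..., parent = NULL) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("feverwatch_transport_error", "error")))
}

#' Open a persistent TCP connection to the server
#'
#' @param endpoint A [server_endpoint()].
#' @param timeout Connection/read timeout (s).
#' @return A socket connection (close with `close()`).
#' @export
telemetry_connect <- function(endpoint, timeout = 10) {
  con <- tryCatch(
    socketConnection(endpoint$ip, endpoint$port, blocking = TRUE,
                     open = "r+", timeout = timeout),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(con)) {
    transport_error("cannot connect to %s:%d", endpoint$ip, endpoint$port)
  }
  con
}

#' Send an event packet over TCP
#'
#' Writes the packet as one newline-delimited UTF-8 JSON line and waits for
#' the server's acknowledgment (the echoed packet id). Connection failures
#' raise a retriable `feverwatch_transport_error` instead of crashing.
#'
#' @param target A [server_endpoint()] (a connection is opened and closed
#'   per call) or an open connection from [telemetry_connect()].
#' @param packet An `event_packet`.
#' @return The acknowledgment string, invisibly.
#' @export
send_event <- function(target, packet) {
  own <- inherits(target, "server_endpoint")
  con <- if (own) telemetry_connect(target) else target
  if (own) on.exit(close(con))
  ok <- tryCatch({
    writeLines(packet_json(packet), con)
    flush(con)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) transport_error("send failed for packet %s", packet$id)
  ack <- tryCatch(readLines(con, n = 1), error = function(e) character(0))
  if (length(ack) != 1) {
    transport_error("no acknowledgment for packet %s", packet$id)
  }
  invisible(ack)
}

#' Run the loopback mock telemetry server
#'
#' Announces itself over UDP (optional), accepts TCP clients, parses each
#' newline-delimited JSON packet, acknowledges it by echoing the packet id,
#' and returns the packets it received. Blocks until `max_packets` arrive or
#' `timeout` elapses; intended to run in a forked child (tests) or from the
#' command line.
#'
#' @param tcp_port TCP listen port.
#' @param udp_port Announcement UDP port, or `NULL` for no announcements.
#' @param announce_ip Address announced (and announced to), loopback by
#'   default.
#' @param announce_interval Seconds between announcements while waiting.
#' @param max_packets Stop after this many packets.
#' @param timeout Overall deadline (s).
#' @param out_file Optional path: received packets are appended as JSON
#'   lines.
#' @return List of received `event_packet`s, invisibly.
#' @export
run_mock_server <- function(tcp_port, udp_port = NULL,
                            announce_ip = "127.0.0.1",
                            announce_interval = 0.2,
                            max_packets = 1L, timeout = 30,
                            out_file = NULL) {
  srv <- serverSocket(as.integer(tcp_port))
  on.exit(close(srv), add = TRUE)
  ufd <- NULL
  if (!is.null(udp_port)) {
    ufd <- .udp_open(0L)
    on.exit(.udp_close(ufd), add = TRUE)
  }
  ann <- announcement_json(announce_ip, tcp_port)
  received <- list()
  deadline <- Sys.time() + timeout
  while (length(received) < max_packets && Sys.time() < deadline) {
    # announce until a client knocks
    client_waiting <- FALSE
    while (Sys.time() < deadline) {
      if (!is.null(ufd)) {
        .udp_send_to(ufd, announce_ip, as.integer(udp_port), ann)
      }
      if (socketSelect(list(srv), timeout = announce_interval)) {
        client_waiting <- TRUE
        break
      }
    }
    if (!client_waiting) break
    con <- socketAccept(srv, blocking = TRUE, open = "r+",
                        timeout = max(1, ceiling(as.numeric(
                          difftime(deadline, Sys.time(), units = "secs")))))
    while (length(received) < max_packets) {
      line <- tryCatch(readLines(con, n = 1), error = function(e) character(0))
      if (length(line) != 1) break  # client gone or timed out
      pkt <- tryCatch(parse_packet(line), error = function(e) NULL)
      if (is.null(pkt)) next  # malformed line: ignore
      received[[length(received) + 1L]] <- pkt
      if (!is.null(out_file)) {
        cat(line, "\n", sep = "", file = out_file, append = TRUE)
      }
      writeLines(pkt$id, con)
      flush(con)
    }
    close(con)
  }
  invisible(received)
}
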