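// Thin POSIX UDP wrapper (base R has TCP sockets only). Used for the
// server-discovery announcements; everything runs on loopback in tests.

#include <Rcpp.h>

#include <arpa/inet.h>
#include <netinet/in.h>
#include <poll.h>
#include <sys/socket.h>
#include <unistd.h>

#include <cerrno>
#include <cstring>

using namespace Rcpp;

// [[Rcpp::export(name = ".udp_open")]]
int udp_open(int port) {
  int fd = socket(AF_INET, SOCK_DGRAM, 0);
  if (fd < 0) stop("udp socket: %s", strerror(errno));
  int one = 1;
  setsockopt(fd, SOL_SOCKET, SO_REUSEADDR, &one, sizeof(one));
  sockaddr_in addr;
  std::memset(&addr, 0, sizeof(addr));
  addr.sin_family = AF_INET;
  addr.sin_addr.s_addr = htonl(INADDR_ANY);
  addr.sin_port = htons((uint16_t)port);
  if (bind(fd, (sockaddr*)&addr, sizeof(addr)) < 0) {
    int e = errno;
    close(fd);
    stop("udp bind to port %d: %s", port, strerror(e));
  }
  return fd;
}

// [[Rcpp::export(name = ".udp_bound_port")]]
int udp_bound_port(int fd) {
  sockaddr_in addr;
  socklen_t len = sizeof(addr);
  if (getsockname(fd, (sockaddr*)&addr, &len) < 0)
    stop("getsockname: %s", strerror(errno));
  return ntohs(addr.sin_port);
}

// [[Rcpp::export(name = ".udp_send_to")]]
bool udp_send_to(int fd, std::string ip, int port, std::string payload) {
  sockaddr_in addr;
  std::memset(&addr, 0, sizeof(addr));
  addr.sin_family = AF_INET;
  addr.sin_port = htons((uint16_t)port);
  if (inet_pton(AF_INET, ip.c_str(), &addr.sin_addr) != 1)
    stop("invalid IPv4 address '%s'", ip.c_str());
  ssize_t n = sendto(fd, payload.data(), payload.size(), 0,
                     (sockaddr*)&addr, sizeof(addr));
  return n == (ssize_t)payload.size();
}

// [[Rcpp::export(name = ".udp_recv_from")]]
SEXP udp_recv_from(int fd, int timeout_ms) {
  pollfd pfd;
  pfd.fd = fd;
  pfd.events = POLLIN;
  int rc;
  do {
    rc = poll(&pfd, 1, timeout_ms);
  } while (rc < 0 && errno == EINTR);  // R's timers interrupt syscalls
  if (rc == 0) return R_NilValue;  // timeout
  if (rc < 0) stop("poll: %s", strerror(errno));
  char buf[65536];
  sockaddr_in from;
  socklen_t fromlen = sizeof(from);
  ssize_t n = recvfrom(fd, buf, sizeof(buf), 0, (sockaddr*)&from, &fromlen);
  if (n < 0) stop("recvfrom: %s", strerror(errno));
  char ip[INET_ADDRSTRLEN];
  inet_ntop(AF_INET, &from.sin_addr, ip, sizeof(ip));
  return List::create(Named("payload") = std::string(buf, (size_t)n),
                      Named("ip") = std::string(ip),
                      Named("port") = (int)ntohs(from.sin_port));
}

// [[Rcpp::export(name = ".udp_close")]]
void udp_close(int fd) { close(fd); }
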