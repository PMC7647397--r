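// Monte Carlo photon transport through a layered cortical scene.
//
// MCML-style weighted packets: at each interaction a fraction mu_a/mu_t of the
// packet weight is deposited locally and the packet continues with weight
// scaled by the single-scattering albedo; sub-threshold packets play Russian
// roulette.  Steps that cross a medium boundary are split at the boundary and
// the remaining optical depth is spent in the next medium, which keeps the
// walk unbiased in layered geometry.  Fluence is tallied with track-length
// estimators.  All randomness flows through R's generator (unif_rand), so a
// single set.seed() makes every run bit-identical.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double T_EPS = 1e-9;   // boundary crossing nudge (mm)
static const double BIG = 1e30;

enum MediumCode {
  MED_TISSUE = 0, MED_GLASS = 1, MED_SKULL = 2, MED_VESSEL = 3,
  EXIT_TOP = 4, EXIT_LATERAL = 5, EXIT_BOTTOM = 6
};

// terminal status codes reported back to R
enum Terminal {
  TERM_ABSORBED = 1, TERM_EXIT_TOP = 2, TERM_EXIT_LATERAL = 3,
  TERM_EXIT_BOTTOM = 4, TERM_CAP = 5
};

struct Scene {
  double vol_radius, tissue_depth;
  double window_radius;      // <= 0: no coverslip anywhere
  double glass_thickness;    // coverslip thickness (inert glass)
  double skull_thickness;    // 0: no skull outside (or instead of) the window
  double mua_t, mus_t, g_t;  // grey matter at the active wavelength
  double mua_sk, mus_sk, g_sk;
  double vessel_radius;      // <= 0: none; cylinder tangent to the surface
  double vessel_offset;      // lateral offset of the axis (mm)
  double vax, vay;           // unit axis direction in the surface plane
};

static Scene scene_from_list(const List& s) {
  Scene sc;
  sc.vol_radius = as<double>(s["vol_radius"]);
  sc.tissue_depth = as<double>(s["tissue_depth"]);
  sc.window_radius = as<double>(s["window_radius"]);
  sc.glass_thickness = as<double>(s["glass_thickness"]);
  sc.skull_thickness = as<double>(s["skull_thickness"]);
  sc.mua_t = as<double>(s["mua_t"]);
  sc.mus_t = as<double>(s["mus_t"]);
  sc.g_t = as<double>(s["g_t"]);
  sc.mua_sk = as<double>(s["mua_sk"]);
  sc.mus_sk = as<double>(s["mus_sk"]);
  sc.g_sk = as<double>(s["g_sk"]);
  sc.vessel_radius = as<double>(s["vessel_radius"]);
  sc.vessel_offset = as<double>(s["vessel_offset"]);
  sc.vax = as<double>(s["vax"]);
  sc.vay = as<double>(s["vay"]);
  return sc;
}

static inline int medium_code(const Scene& sc, double x, double y, double z) {
  if (z >= sc.tissue_depth) return EXIT_BOTTOM;
  double r2 = x * x + y * y;
  if (r2 >= sc.vol_radius * sc.vol_radius) return EXIT_LATERAL;
  if (z >= 0.0) {
    if (sc.vessel_radius > 0.0) {
      // cylinder axis horizontal along (vax, vay) at perpendicular offset
      double perp = x * sc.vay - y * sc.vax - sc.vessel_offset;
      double dz = z - sc.vessel_radius;
      if (perp * perp + dz * dz <= sc.vessel_radius * sc.vessel_radius)
        return MED_VESSEL;
    }
    return MED_TISSUE;
  }
  if (sc.window_radius > 0.0 && r2 <= sc.window_radius * sc.window_radius) {
    if (z >= -sc.glass_thickness) return MED_GLASS;
    return EXIT_TOP;
  }
  if (sc.skull_thickness > 0.0 && z >= -sc.skull_thickness) return MED_SKULL;
  return EXIT_TOP;
}

// smallest t > T_EPS with (p + t d) on the circle of radius R (2-D sub-problem)
static inline double ray_circle(double px, double py, double dx, double dy,
                                double R) {
  double a = dx * dx + dy * dy;
  if (a < 1e-20) return BIG;
  double b = px * dx + py * dy;
  double c = px * px + py * py - R * R;
  double disc = b * b - a * c;
  if (disc < 0.0) return BIG;
  double sq = std::sqrt(disc);
  double t1 = (-b - sq) / a;
  if (t1 > T_EPS) return t1;
  double t2 = (-b + sq) / a;
  if (t2 > T_EPS) return t2;
  return BIG;
}

static double boundary_distance(const Scene& sc, double x, double y, double z,
                                double ux, double uy, double uz) {
  double t = BIG, cand;
  if (std::fabs(uz) > 1e-20) {
    cand = (0.0 - z) / uz;
    if (cand > T_EPS && cand < t) t = cand;
    cand = (sc.tissue_depth - z) / uz;
    if (cand > T_EPS && cand < t) t = cand;
    cand = (-sc.glass_thickness - z) / uz;
    if (cand > T_EPS && cand < t) t = cand;
    cand = (-sc.skull_thickness - z) / uz;
    if (cand > T_EPS && cand < t) t = cand;
  }
  cand = ray_circle(x, y, ux, uy, sc.vol_radius);
  if (cand < t) t = cand;
  if (z <= 0.0 && sc.window_radius > 0.0) {
    cand = ray_circle(x, y, ux, uy, sc.window_radius);
    if (cand < t) t = cand;
  }
  if (sc.vessel_radius > 0.0) {
    // project onto the plane perpendicular to the vessel axis
    double perp = x * sc.vay - y * sc.vax - sc.vessel_offset;
    double dperp = ux * sc.vay - uy * sc.vax;
    cand = ray_circle(perp, z - sc.vessel_radius, dperp, uz, sc.vessel_radius);
    if (cand < t) t = cand;
  }
  return t;
}

struct Recorders {
  bool on;
  double pitch;
  int nz, nr;
  double profile_radius;           // restrict depth profile to r <= this
  double col_half_width, col_half_len;
  double cax, cay;                 // column axis (the vessel axis)
  double col_offset;
  std::vector<double> fl_z, cz_z, fl_rz, col_z;

  void init(double pitch_, int nz_, int nr_, double prof_r,
            double chw, double chl, double cax_, double cay_, double coff) {
    on = true;
    pitch = pitch_; nz = nz_; nr = nr_;
    profile_radius = prof_r;
    col_half_width = chw; col_half_len = chl;
    cax = cax_; cay = cay_; col_offset = coff;
    fl_z.assign(nz, 0.0);
    cz_z.assign(nz, 0.0);
    fl_rz.assign(nr > 0 ? (size_t)nz * nr : 0, 0.0);
    col_z.assign(nz, 0.0);
  }

  // track-length tally of a straight tissue segment, split across z bins
  void segment(double x, double y, double z, double ux, double uy, double uz,
               double len, double w) {
    double remaining = len, t0 = 0.0;
    int guard = 0;
    while (remaining > 1e-13 && guard++ < 4 * nz + 8) {
      double zc = z + t0 * uz;
      int iz = (int)std::floor(zc / pitch);
      if (iz < 0) iz = 0;
      if (iz >= nz) iz = nz - 1;
      double t_seg;
      if (std::fabs(uz) < 1e-12) {
        t_seg = remaining;
      } else {
        double zb = (uz > 0.0 ? (iz + 1) * pitch : iz * pitch);
        t_seg = (zb - zc) / uz;
        if (t_seg > remaining) t_seg = remaining;
        if (t_seg < 1e-12) t_seg = 1e-12;
      }
      double tm = t0 + 0.5 * t_seg;
      double xm = x + tm * ux, ym = y + tm * uy;
      double r2m = xm * xm + ym * ym;
      double wl = w * t_seg;
      if (r2m <= profile_radius * profile_radius) {
        fl_z[iz] += wl;
        cz_z[iz] += wl * uz;
      }
      if (nr > 0) {
        int ir = (int)std::floor(std::sqrt(r2m) / pitch);
        if (ir < nr) fl_rz[(size_t)iz * nr + ir] += wl;
      }
      if (col_half_width > 0.0) {
        double perp = xm * cay - ym * cax - col_offset;
        double along = xm * cax + ym * cay;
        if (std::fabs(perp) <= col_half_width &&
            std::fabs(along) <= col_half_len)
          col_z[iz] += wl;
      }
      t0 += t_seg;
      remaining -= t_seg;
    }
  }
};

struct Accounting {
  double launched = 0.0, deposited = 0.0, exit_top = 0.0, exit_lat = 0.0,
         exit_bot = 0.0, roulette_net = 0.0, cap_killed = 0.0;
  long n_cap = 0;
};

static inline void hg_scatter(double g, double& ux, double& uy, double& uz) {
  double u = unif_rand();
  double ct;
  if (std::fabs(g) < 1e-12) {
    ct = 2.0 * u - 1.0;
  } else {
    double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
    ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
    if (ct > 1.0) ct = 1.0;
    else if (ct < -1.0) ct = -1.0;
  }
  double st = std::sqrt(1.0 - ct * ct);
  double phi = 2.0 * M_PI * unif_rand();
  double cp = std::cos(phi), sp = std::sin(phi);
  double nx, ny, nz;
  if (std::fabs(uz) > 0.99999) {
    nx = st * cp;
    ny = st * sp;
    nz = ct * (uz >= 0.0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    nz = -st * cp * den + uz * ct;
  }
  double n2 = nx * nx + ny * ny + nz * nz;
  if (std::fabs(n2 - 1.0) > 1e-12) {
    double inv = 1.0 / std::sqrt(n2);
    nx *= inv; ny *= inv; nz *= inv;
  }
  ux = nx; uy = ny; uz = nz;
}

struct Terminals {
  bool on = false;
  std::vector<double> buf;  // status, x, y, z, ux, uy, uz, w
  void push(int status, double x, double y, double z,
            double ux, double uy, double uz, double w) {
    if (!on) return;
    buf.push_back((double)status);
    buf.push_back(x); buf.push_back(y); buf.push_back(z);
    buf.push_back(ux); buf.push_back(uy); buf.push_back(uz);
    buf.push_back(w);
  }
};

static void propagate_one(const Scene& sc, double x, double y, double z,
                          double ux, double uy, double uz, double w,
                          Recorders* rec, Accounting& acc,
                          std::vector<double>* exits, Terminals& term,
                          int max_steps, double w_min, double p_surv) {
  acc.launched += w;
  double tau = -std::log(unif_rand());
  int steps = 0;
  while (true) {
    if (++steps > max_steps) {
      acc.cap_killed += w;
      acc.n_cap++;
      term.push(TERM_CAP, x, y, z, ux, uy, uz, 0.0);
      return;
    }
    int med = medium_code(sc, x + T_EPS * ux, y + T_EPS * uy, z + T_EPS * uz);
    if (med >= EXIT_TOP) {
      if (med == EXIT_TOP) {
        acc.exit_top += w;
        if (exits) {
          exits->push_back(x); exits->push_back(y); exits->push_back(z);
          exits->push_back(ux); exits->push_back(uy); exits->push_back(uz);
          exits->push_back(w);
        }
        term.push(TERM_EXIT_TOP, x, y, z, ux, uy, uz, w);
      } else if (med == EXIT_LATERAL) {
        acc.exit_lat += w;
        term.push(TERM_EXIT_LATERAL, x, y, z, ux, uy, uz, w);
      } else {
        acc.exit_bot += w;
        term.push(TERM_EXIT_BOTTOM, x, y, z, ux, uy, uz, w);
      }
      return;
    }
    if (med == MED_VESSEL) {
      // totally absorbing vessel: deposit all remaining weight
      acc.deposited += w;
      term.push(TERM_ABSORBED, x, y, z, ux, uy, uz, 0.0);
      return;
    }
    double mua = 0.0, mus = 0.0, g = 0.0;
    if (med == MED_TISSUE) { mua = sc.mua_t; mus = sc.mus_t; g = sc.g_t; }
    else if (med == MED_SKULL) { mua = sc.mua_sk; mus = sc.mus_sk; g = sc.g_sk; }
    double mut = mua + mus;
    double db = boundary_distance(sc, x, y, z, ux, uy, uz);
    double s;
    bool interact;
    if (mut <= 0.0) {
      s = db + T_EPS;
      interact = false;
    } else {
      s = tau / mut;
      if (s < db) {
        interact = true;
      } else {
        s = db + T_EPS;
        tau -= s * mut;
        if (tau < 0.0) tau = 0.0;
        interact = false;
      }
    }
    if (rec && rec->on && med == MED_TISSUE && z >= 0.0)
      rec->segment(x, y, z, ux, uy, uz, s, w);
    x += s * ux; y += s * uy; z += s * uz;
    if (interact) {
      acc.deposited += w * mua / mut;
      w *= mus / mut;
      if (w <= 0.0) {
        term.push(TERM_ABSORBED, x, y, z, ux, uy, uz, 0.0);
        return;
      }
      if (w < w_min) {
        if (unif_rand() < p_surv) {
          acc.roulette_net -= w * (1.0 / p_surv - 1.0);
          w /= p_surv;
        } else {
          acc.roulette_net += w;
          term.push(TERM_ABSORBED, x, y, z, ux, uy, uz, 0.0);
          return;
        }
      }
      hg_scatter(g, ux, uy, uz);
      tau = -std::log(unif_rand());
    }
  }
}

static List pack_results(const Scene& sc, const Recorders& rec,
                         const Accounting& acc,
                         const std::vector<double>& exits, bool keep_exits,
                         const Terminals& term) {
  List out;
  out["accounting"] = NumericVector::create(
      _["launched"] = acc.launched, _["deposited"] = acc.deposited,
      _["exited_top"] = acc.exit_top, _["exited_lateral"] = acc.exit_lat,
      _["exited_bottom"] = acc.exit_bot, _["roulette_net"] = acc.roulette_net,
      _["cap_killed"] = acc.cap_killed);
  out["n_step_cap"] = (double)acc.n_cap;
  if (rec.on) {
    out["fluence_z"] = NumericVector(rec.fl_z.begin(), rec.fl_z.end());
    out["cos_sum_z"] = NumericVector(rec.cz_z.begin(), rec.cz_z.end());
    out["column_z"] = NumericVector(rec.col_z.begin(), rec.col_z.end());
    if (rec.nr > 0) {
      NumericMatrix m(rec.nz, rec.nr);
      for (int iz = 0; iz < rec.nz; ++iz)
        for (int ir = 0; ir < rec.nr; ++ir)
          m(iz, ir) = rec.fl_rz[(size_t)iz * rec.nr + ir];
      out["fluence_rz"] = m;
    }
  }
  if (keep_exits) {
    size_t n = exits.size() / 7;
    NumericMatrix e(n, 7);
    for (size_t i = 0; i < n; ++i)
      for (int j = 0; j < 7; ++j) e(i, j) = exits[7 * i + j];
    colnames(e) = CharacterVector::create("x", "y", "z", "ux", "uy", "uz",
                                          "w");
    out["exits"] = e;
  }
  if (term.on) {
    size_t n = term.buf.size() / 8;
    NumericMatrix t(n, 8);
    for (size_t i = 0; i < n; ++i)
      for (int j = 0; j < 8; ++j) t(i, j) = term.buf[8 * i + j];
    colnames(t) = CharacterVector::create("status", "x", "y", "z",
                                          "ux", "uy", "uz", "w");
    out["terminals"] = t;
  }
  return out;
}

// Direction autocorrelation of the compiled scatter kernel: mean z-component
// after k successive deflections of an initially +z direction. Equals g^k
// for Henyey-Greenstein scattering; used to validate the compiled sampler.
// [[Rcpp::export]]
NumericVector hg_autocorrelation(int n, double g, int k_max) {
  NumericVector out(k_max);
  for (int i = 0; i < n; ++i) {
    double ux = 0.0, uy = 0.0, uz = 1.0;
    for (int k = 0; k < k_max; ++k) {
      hg_scatter(g, ux, uy, uz);
      out[k] += uz;
    }
  }
  for (int k = 0; k < k_max; ++k) out[k] /= n;
  return out;
}

// Propagate caller-supplied packets (illumination entries, unit tests).
// [[Rcpp::export]]
List mc_transport(List scene, NumericMatrix pos, NumericMatrix dir,
                  NumericVector w, bool record, double pitch, int nz, int nr,
                  double profile_radius, double col_half_width,
                  double col_half_len, bool keep_exits, bool terminals,
                  int max_steps, double w_min, double p_surv) {
  Scene sc = scene_from_list(scene);
  Recorders rec;
  rec.on = false;
  if (record)
    rec.init(pitch, nz, nr, profile_radius, col_half_width, col_half_len,
             sc.vax, sc.vay, sc.vessel_offset);
  Accounting acc;
  std::vector<double> exits;
  Terminals term;
  term.on = terminals;
  int n = pos.nrow();
  for (int i = 0; i < n; ++i) {
    propagate_one(sc, pos(i, 0), pos(i, 1), pos(i, 2), dir(i, 0), dir(i, 1),
                  dir(i, 2), w[i], record ? &rec : (Recorders*)0, acc,
                  keep_exits ? &exits : (std::vector<double>*)0, term,
                  max_steps, w_min, p_surv);
    if ((i & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return pack_results(sc, rec, acc, exits, keep_exits, term);
}

// Isotropic point source at (0, 0, depth): the fluorescence-emission case.
// [[Rcpp::export]]
List mc_point_source(List scene, double depth, int n, bool record,
                     double pitch, int nz, int nr, double profile_radius,
                     double col_half_width, double col_half_len,
                     bool keep_exits, bool terminals, int max_steps,
                     double w_min, double p_surv) {
  Scene sc = scene_from_list(scene);
  Recorders rec;
  rec.on = false;
  if (record)
    rec.init(pitch, nz, nr, profile_radius, col_half_width, col_half_len,
             sc.vax, sc.vay, sc.vessel_offset);
  Accounting acc;
  std::vector<double> exits;
  Terminals term;
  term.on = terminals;
  for (int i = 0; i < n; ++i) {
    double uz = 2.0 * unif_rand() - 1.0;
    double st = std::sqrt(1.0 - uz * uz);
    double phi = 2.0 * M_PI * unif_rand();
    propagate_one(sc, 0.0, 0.0, depth, st * std::cos(phi), st * std::sin(phi),
                  uz, 1.0, record ? &rec : (Recorders*)0, acc,
                  keep_exits ? &exits : (std::vector<double>*)0, term,
                  max_steps, w_min, p_surv);
    if ((i & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return pack_results(sc, rec, acc, exits, keep_exits, term);
}
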