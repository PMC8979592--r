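// Stochastic structure-resolved reaction-diffusion propagator.
//
// Units: nm, us, k_B T. Molecules are rigid bodies with interface sites;
// complexes (connected bond graphs) diffuse rigidly with aggregate transport
// coefficients. Per step: 0th-order creation / 1st-order destruction
// (reservoir), bond dissociation, implicit-site exchange, pairwise binding
// with Green's-function (3D) or reactive-annulus (2D) probabilities plus
// orientation snapping, then rigid-body Brownian moves with excluded-volume
// rejection. Randomness comes from R's RNG so runs are seed-reproducible.

#include <Rcpp.h>
#include <chrono>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------- small vector / quaternion algebra --------------------------------

struct Vec3 {
  double x = 0, y = 0, z = 0;
  Vec3() {}
  Vec3(double a, double b, double c) : x(a), y(b), z(c) {}
  Vec3 operator+(const Vec3& o) const { return {x + o.x, y + o.y, z + o.z}; }
  Vec3 operator-(const Vec3& o) const { return {x - o.x, y - o.y, z - o.z}; }
  Vec3 operator*(double s) const { return {x * s, y * s, z * s}; }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3& o) const {
    return {y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x};
  }
  double norm() const { return std::sqrt(x * x + y * y + z * z); }
};

struct Quat {
  double w = 1, x = 0, y = 0, z = 0;
  Quat() {}
  Quat(double a, double b, double c, double d) : w(a), x(b), y(c), z(d) {}
  Quat operator*(const Quat& o) const {
    return {w * o.w - x * o.x - y * o.y - z * o.z,
            w * o.x + x * o.w + y * o.z - z * o.y,
            w * o.y - x * o.z + y * o.w + z * o.x,
            w * o.z + x * o.y - y * o.x + z * o.w};
  }
  void normalize() {
    double n = std::sqrt(w * w + x * x + y * y + z * z);
    w /= n; x /= n; y /= n; z /= n;
  }
  Vec3 rotate(const Vec3& v) const {
    Vec3 u{x, y, z};
    Vec3 uv = u.cross(v);
    Vec3 uuv = u.cross(uv);
    return v + (uv * w + uuv) * 2.0;
  }
};

static Quat quat_axis_angle(const Vec3& axis, double angle) {
  double n = axis.norm();
  if (n < 1e-12) return Quat();
  double s = std::sin(angle / 2) / n;
  return {std::cos(angle / 2), axis.x * s, axis.y * s, axis.z * s};
}

static Quat quat_between(Vec3 u, Vec3 v) {
  double nu = u.norm(), nv = v.norm();
  u = u * (1.0 / nu); v = v * (1.0 / nv);
  double d = u.dot(v);
  if (d > 1 - 1e-12) return Quat();
  if (d < -1 + 1e-12) {
    Vec3 p = std::fabs(u.x) < 0.9 ? Vec3(1, 0, 0) : Vec3(0, 1, 0);
    return quat_axis_angle(u.cross(p), M_PI);
  }
  Vec3 ax = u.cross(v);
  Quat q{1 + d, ax.x, ax.y, ax.z};
  q.normalize();
  return q;
}

// ---------- association probabilities ----------------------------------------

// scaled complementary error function, exp(z^2) erfc(z), z >= 0
static double erfcx_(double z) {
  if (z < 6.0) return std::exp(z * z) * std::erfc(z);
  double iz2 = 1.0 / (z * z);
  return (1.0 - 0.5 * iz2 * (1.0 - 1.5 * iz2 * (1.0 - 2.5 * iz2))) /
         (z * std::sqrt(M_PI));
}

// Association probability over dt for an isolated pair at separation r,
// radiation boundary at sigma with intrinsic rate ka (nm^3/us), relative
// diffusion D (nm^2/us). Exact for the irreversible Smoluchowski pair.
static double gf3d_prob(double r, double ka, double D, double sigma,
                        double dt) {
  if (ka <= 0 || dt <= 0) return 0.0;
  if (r < sigma) r = sigma;
  double kD = 4.0 * M_PI * sigma * D;
  double a = (1.0 + ka / kD) / sigma;
  double sdt = std::sqrt(D * dt);
  double x = (r - sigma) / (2.0 * sdt);
  double y = a * sdt;
  double term = std::erfc(x) - erfcx_(x + y) * std::exp(-x * x);
  double p = ka / (ka + kD) * (sigma / r) * term;
  if (p < 0) p = 0;
  if (p > 1) p = 1;
  return p;
}

// [[Rcpp::export]]
double p_bind_3d_cpp(double r, double ka_nm3us, double D_nm2us,
                     double sigma, double dt_us) {
  return gf3d_prob(r, ka_nm3us, D_nm2us, sigma, dt_us);
}

// ---------- model data --------------------------------------------------------

struct Template {
  int nsite = 0;
  std::vector<Vec3> local;
  std::vector<int> cls;
  std::vector<double> excl;
  double com_excl = 0;
  Vec3 D, DR;
  double max_ext = 0;
  bool anchored = false;          // species confined to the membrane plane
};

struct Channel {
  int c1 = -1, c2 = -1;
  double ka3 = 0;                 // nm^3/us
  double ka2 = -1;                // nm^2/us (<0: no 2D form)
  double kb = 0;                  // 1/us
  double sigma = 1;
  bool coop = false;
  bool ring = false;
  bool memonly = false;           // evaluated only with a membrane partner
};

struct Molecule {
  int type = 0;
  Vec3 pos;
  Quat q;
  int comp = -1;
  bool alive = false;
  std::vector<int> partner;       // 64*mol+site, -1 free, -2 implicit site
  std::vector<Vec3> sg;           // cached global site positions
};

struct Complexo {
  std::vector<int> members;
  Vec3 D, DR;
  double ext = 0;                 // max member distance from centroid, nm
  int anchors = 0;                // implicit-site bonds (lipid drag each)
  bool planar = false;            // contains a membrane-confined species
  bool alive = false;
  bool reacted = false;
};

struct Sim {
  double Lx = 0, Ly = 0, Lz = 0, dt = 3;
  bool periodic_z = false;        // bulk fixtures: no membrane, no walls
  double delta2d = 1.0;
  double max_rot = 17.0;
  double f_coop = 1.0;
  bool coop_either = true;
  double ring_cutoff = 5.5;
  double exp_neg_strain = 1.0;
  int coop_marker_class = -1;
  long n_imp_sites = 0, imp_occupied = 0;
  int imp_class = -1;
  double imp_ka = 0, imp_kb = 0, imp_h = 4.0, imp_site_z = 4.0;
  int res_type = -1;
  double res_target = 0, res_kd = 0;
  std::vector<Template> tpl;
  std::vector<Channel> chan;
  std::vector<Molecule> mol;
  std::vector<Complexo> comp;
  std::vector<int> free_mol, free_comp;
  double lipid_D = 0.5, lipid_DRz = 0.01;
  double t = 0;
  long step_count = 0;
  double scan_reval = 100;
  int ring_every = 4;             // closure attempts evaluated on a stride
  double n_rej_steric = 0, n_rej_rot = 0, n_events = 0;
  double n_bind_accept = 0, n_snap_fail = 0;
  double t_res = 0, t_dis = 0, t_cells = 0, t_imp = 0, t_scan = 0,
         t_apply = 0, t_diff = 0;
  std::chrono::high_resolution_clock::time_point tp_;
  void tic() { tp_ = std::chrono::high_resolution_clock::now(); }
  double toc() {
    auto now = std::chrono::high_resolution_clock::now();
    return std::chrono::duration<double>(now - tp_).count();
  }
  // reusable scratch (hot loops must not allocate)
  std::vector<int> sb_ids;
  std::vector<Vec3> sb_pos;
  std::vector<Quat> sb_quat;

  int chan_lut[16][16];
  bool cls_reactive[16];
  void build_chan_lut() {
    for (int a = 0; a < 16; ++a) {
      cls_reactive[a] = false;
      for (int b = 0; b < 16; ++b) chan_lut[a][b] = -1;
    }
    for (size_t k = 0; k < chan.size(); ++k) {
      chan_lut[chan[k].c1][chan[k].c2] = (int)k;
      chan_lut[chan[k].c2][chan[k].c1] = (int)k;
      cls_reactive[chan[k].c1] = true;
      cls_reactive[chan[k].c2] = true;
    }
  }

  // any unbound site that can participate in a pairwise channel?
  bool has_free_rx(int im) const {
    const Molecule& m = mol[im];
    const Template& T = tpl[m.type];
    for (int s = 0; s < T.nsite; ++s)
      if (m.partner[s] == -1 && cls_reactive[T.cls[s]]) return true;
    return false;
  }
  int chan_of(int a, int b) const { return chan_lut[a][b]; }

  // per-template-pair early-out radius for the steric scan
  std::vector<double> steric_range;  // ntpl x ntpl
  void build_steric_range() {
    size_t nt = tpl.size();
    steric_range.assign(nt * nt, 0.0);
    for (size_t a = 0; a < nt; ++a)
      for (size_t b = 0; b < nt; ++b) {
        double r = std::min(tpl[a].com_excl, tpl[b].com_excl);
        double mx_ex = 0;
        for (double e : tpl[a].excl) mx_ex = std::max(mx_ex, e);
        for (double e : tpl[b].excl) mx_ex = std::max(mx_ex, e);
        r = std::max(r, mx_ex + tpl[a].max_ext + tpl[b].max_ext);
        steric_range[a * nt + b] = r;
      }
  }

  double wrapdx(double d, double L) const {
    if (d > 0.5 * L) d -= L; else if (d < -0.5 * L) d += L;
    return d;
  }
  Vec3 mind(const Vec3& a, const Vec3& b) const {
    return {wrapdx(a.x - b.x, Lx), wrapdx(a.y - b.y, Ly),
            periodic_z ? wrapdx(a.z - b.z, Lz) : a.z - b.z};
  }

  void cache_sites(int im) {
    Molecule& m = mol[im];
    const Template& T = tpl[m.type];
    m.sg.resize(T.nsite);
    for (int s = 0; s < T.nsite; ++s)
      m.sg[s] = m.q.rotate(T.local[s]) + m.pos;
  }

  bool adaptor_bound(int im) const {
    const Molecule& m = mol[im];
    const Template& T = tpl[m.type];
    for (int s = 0; s < T.nsite; ++s)
      if (T.cls[s] == coop_marker_class && m.partner[s] != -1) return true;
    return false;
  }

  bool on_mem(int ic) const {
    return comp[ic].anchors > 0 || comp[ic].planar;
  }

  void update_D(int ic) {
    Complexo& c = comp[ic];
    double ix = 0, iy = 0, iz = 0, rx = 0, ry = 0, rz = 0;
    bool zx = false, zy = false, zz = false;
    for (int im : c.members) {
      const Template& T = tpl[mol[im].type];
      ix += 1.0 / T.D.x; iy += 1.0 / T.D.y; iz += 1.0 / T.D.z;
      if (T.DR.x <= 0) zx = true; else rx += std::pow(T.DR.x, -1.0 / 3);
      if (T.DR.y <= 0) zy = true; else ry += std::pow(T.DR.y, -1.0 / 3);
      if (T.DR.z <= 0) zz = true; else rz += std::pow(T.DR.z, -1.0 / 3);
    }
    for (int a = 0; a < c.anchors; ++a) {
      ix += 1.0 / lipid_D; iy += 1.0 / lipid_D;
      zx = true; zy = true;
      rz += std::pow(lipid_DRz, -1.0 / 3);
    }
    bool mem = c.anchors > 0 || c.planar;
    Vec3 cen;
    for (int im : c.members) cen = cen + mol[im].pos;
    cen = cen * (1.0 / c.members.size());
    c.ext = 0;
    for (int im : c.members)
      c.ext = std::max(c.ext, (mol[im].pos - cen).norm());
    c.D = {1.0 / ix, 1.0 / iy, mem ? 0.0 : 1.0 / iz};
    c.DR = {zx ? 0.0 : std::pow(rx, -3.0), zy ? 0.0 : std::pow(ry, -3.0),
            zz ? 0.0 : std::pow(rz, -3.0)};
    if (mem) { c.DR.x = 0; c.DR.y = 0; }
  }

  int new_complex_slot() {
    int ic;
    if (!free_comp.empty()) { ic = free_comp.back(); free_comp.pop_back(); }
    else { comp.push_back(Complexo()); ic = (int)comp.size() - 1; }
    comp[ic] = Complexo();
    comp[ic].alive = true;
    return ic;
  }

  int new_molecule(int type, const Vec3& p, const Quat& q) {
    int im;
    if (!free_mol.empty()) { im = free_mol.back(); free_mol.pop_back(); }
    else { mol.push_back(Molecule()); im = (int)mol.size() - 1; }
    Molecule& m = mol[im];
    m = Molecule();
    m.type = type; m.pos = p; m.q = q; m.alive = true;
    m.partner.assign(tpl[type].nsite, -1);
    int ic = new_complex_slot();
    comp[ic].members.assign(1, im);
    m.comp = ic;
    update_anchors(ic);
    cache_sites(im);
    return im;
  }

  void destroy_molecule(int im) {
    int ic = mol[im].comp;
    mol[im].alive = false;
    free_mol.push_back(im);
    comp[ic].alive = false;
    comp[ic].members.clear();
    free_comp.push_back(ic);
  }

  // ------ cell list over molecules -------------------------------------------
  int ncx = 1, ncy = 1, ncz = 1;
  double cell = 100;
  std::vector<std::vector<int>> cells;
  std::vector<int> used_cells;
  std::vector<int> alive_list;    // direct iteration for small systems

  void build_cells(double range) {
    cell = std::max(range, 1.0);
    int nx = std::max(1, (int)std::floor(Lx / cell));
    int ny = std::max(1, (int)std::floor(Ly / cell));
    int nz = std::max(1, (int)std::floor(Lz / cell));
    size_t need = (size_t)nx * ny * nz;
    if (nx != ncx || ny != ncy || nz != ncz || cells.size() != need) {
      ncx = nx; ncy = ny; ncz = nz;
      cells.assign(need, {});
      used_cells.clear();
    } else {
      for (int c : used_cells) cells[c].clear();
      used_cells.clear();
    }
    alive_list.clear();
    for (size_t im = 0; im < mol.size(); ++im) {
      if (!mol[im].alive) continue;
      alive_list.push_back((int)im);
      int c = cell_of(mol[im].pos);
      if (cells[c].empty()) used_cells.push_back(c);
      cells[c].push_back((int)im);
    }
  }
  int cell_of(const Vec3& p) const {
    int i = (int)std::floor(p.x / cell); i = ((i % ncx) + ncx) % ncx;
    int j = (int)std::floor(p.y / cell); j = ((j % ncy) + ncy) % ncy;
    int k = (int)std::floor(p.z / cell);
    if (periodic_z) k = ((k % ncz) + ncz) % ncz;
    if (k < 0) k = 0;
    if (k >= ncz) k = ncz - 1;
    return (i * ncy + j) * ncz + k;
  }
  template <class F> void for_neighbors(const Vec3& p, F f) const {
    if (alive_list.size() < 60) {    // direct scan beats cell overhead
      for (int im : alive_list) f(im);
      return;
    }
    int ci = (int)std::floor(p.x / cell), cj = (int)std::floor(p.y / cell),
        ck = (int)std::floor(p.z / cell);
    int dxlo = ncx >= 3 ? -1 : 0, dxhi = ncx >= 2 ? 1 : 0;
    int dylo = ncy >= 3 ? -1 : 0, dyhi = ncy >= 2 ? 1 : 0;
    int dzlo = -1, dzhi = 1;
    if (periodic_z) { dzlo = ncz >= 3 ? -1 : 0; dzhi = ncz >= 2 ? 1 : 0; }
    for (int di = dxlo; di <= dxhi; ++di)
      for (int dj = dylo; dj <= dyhi; ++dj)
        for (int dk = dzlo; dk <= dzhi; ++dk) {
          int i = (((ci + di) % ncx) + ncx) % ncx;
          int j = (((cj + dj) % ncy) + ncy) % ncy;
          int k = ck + dk;
          if (periodic_z) k = ((k % ncz) + ncz) % ncz;
          if (k < 0 || k >= ncz) continue;
          for (int im : cells[(size_t)(i * ncy + j) * ncz + k]) f(im);
        }
  }

  // ------ steric checks ------------------------------------------------------

  bool mol_overlaps(int im) {
    const Molecule& m = mol[im];
    const Template& Tm = tpl[m.type];
    bool bad = false;
    for_neighbors(m.pos, [&](int jm) {
      if (bad || jm == im) return;
      const Molecule& o = mol[jm];
      if (!o.alive || o.comp == m.comp) return;
      const Template& To = tpl[o.type];
      Vec3 d = mind(m.pos, o.pos);
      double rng = steric_range[m.type * tpl.size() + o.type];
      if (d.dot(d) > rng * rng) return;
      double rex = std::min(Tm.com_excl, To.com_excl);
      if (rex > 0 && d.dot(d) < rex * rex * (1 - 1e-12)) {
        bad = true; return;
      }
      for (int s = 0; s < Tm.nsite; ++s) {
        if (m.partner[s] != -1) continue;
        for (int u = 0; u < To.nsite; ++u) {
          if (o.partner[u] != -1) continue;
          int k = chan_of(Tm.cls[s], To.cls[u]);
          if (k < 0) continue;
          double ex = std::min(Tm.excl[s], To.excl[u]);
          if (ex <= 0) continue;
          Vec3 ds = mind(m.sg[s], o.sg[u]);
          if (ds.dot(ds) < ex * ex * (1 - 1e-12)) { bad = true; return; }
        }
      }
    });
    return bad;
  }

  bool internal_overlap(int ic) {
    const std::vector<int>& mem = comp[ic].members;
    for (size_t a = 0; a + 1 < mem.size(); ++a)
      for (size_t b = a + 1; b < mem.size(); ++b) {
        const Molecule& ma = mol[mem[a]], &mb = mol[mem[b]];
        double rex = std::min(tpl[ma.type].com_excl, tpl[mb.type].com_excl);
        if (rex <= 0) continue;
        if (directly_bonded(mem[a], mem[b])) continue;
        Vec3 d = mind(ma.pos, mb.pos);
        if (d.dot(d) < rex * rex * (1 - 1e-9)) return true;
      }
    return false;
  }

  bool directly_bonded(int a, int b) const {
    const Molecule& ma = mol[a];
    for (size_t s = 0; s < ma.partner.size(); ++s)
      if (ma.partner[s] >= 0 && ma.partner[s] / 64 == b) return true;
    return false;
  }

  // ------ rigid transforms ---------------------------------------------------

  void move_complex(int ic, const Vec3& dr, const Quat& rot,
                    const Vec3& center) {
    for (int im : comp[ic].members) {
      Molecule& m = mol[im];
      m.pos = rot.rotate(m.pos - center) + center + dr;
      m.q = rot * m.q; m.q.normalize();
      cache_sites(im);
    }
  }

  Vec3 centroid(int ic) const {
    Vec3 c;
    for (int im : comp[ic].members) c = c + mol[im].pos;
    return c * (1.0 / comp[ic].members.size());
  }

  void wrap_complex(int ic) {
    Vec3 c = centroid(ic);
    double sx = 0, sy = 0, sz = 0;
    if (c.x < 0) sx = Lx; else if (c.x >= Lx) sx = -Lx;
    if (c.y < 0) sy = Ly; else if (c.y >= Ly) sy = -Ly;
    if (periodic_z) {
      if (c.z < 0) sz = Lz; else if (c.z >= Lz) sz = -Lz;
    }
    if (sx != 0 || sy != 0 || sz != 0)
      for (int im : comp[ic].members) {
        mol[im].pos.x += sx; mol[im].pos.y += sy; mol[im].pos.z += sz;
        cache_sites(im);
      }
  }

  void save_pose(int ic, std::vector<int>& ids, std::vector<Vec3>& ps,
                 std::vector<Quat>& qs) const {
    ids = comp[ic].members;
    ps.clear(); qs.clear();
    for (int im : ids) { ps.push_back(mol[im].pos); qs.push_back(mol[im].q); }
  }
  void restore_pose(const std::vector<int>& ids, const std::vector<Vec3>& ps,
                    const std::vector<Quat>& qs) {
    for (size_t a = 0; a < ids.size(); ++a) {
      mol[ids[a]].pos = ps[a]; mol[ids[a]].q = qs[a];
      cache_sites(ids[a]);
    }
  }

  void bind_sites(int im, int s, int jm, int u) {
    mol[im].partner[s] = jm * 64 + u;
    mol[jm].partner[u] = im * 64 + s;
  }
  void unbind_sites(int im, int s, int jm, int u) {
    mol[im].partner[s] = -1;
    mol[jm].partner[u] = -1;
  }

  void merge_complexes(int ic1, int ic2) {
    if (ic1 == ic2) return;
    Complexo& a = comp[ic1];
    Complexo& b = comp[ic2];
    for (int im : b.members) { mol[im].comp = ic1; a.members.push_back(im); }
    a.anchors += b.anchors;
    a.planar = a.planar || b.planar;
    a.reacted = a.reacted || b.reacted;
    b.alive = false; b.members.clear();
    free_comp.push_back(ic2);
    update_D(ic1);
  }

  void split_complex(int ic) {
    std::vector<int> mem = comp[ic].members;
    std::vector<char> seen(mem.size(), 0);
    std::vector<std::vector<int>> parts;
    for (size_t a = 0; a < mem.size(); ++a) {
      if (seen[a]) continue;
      std::vector<int> part, stack{(int)a};
      seen[a] = 1;
      while (!stack.empty()) {
        int cur = stack.back(); stack.pop_back();
        part.push_back(mem[cur]);
        const Molecule& mc = mol[mem[cur]];
        for (size_t s = 0; s < mc.partner.size(); ++s) {
          if (mc.partner[s] < 0) continue;
          int other = mc.partner[s] / 64;
          for (size_t b = 0; b < mem.size(); ++b)
            if (mem[b] == other && !seen[b]) {
              seen[b] = 1; stack.push_back((int)b);
            }
        }
      }
      parts.push_back(part);
    }
    comp[ic].members = parts[0];
    for (int im : parts[0]) mol[im].comp = ic;
    update_anchors(ic);
    for (size_t pI = 1; pI < parts.size(); ++pI) {
      int nc = new_complex_slot();
      comp[nc].members = parts[pI];
      comp[nc].reacted = comp[ic].reacted;
      for (int im : parts[pI]) mol[im].comp = nc;
      update_anchors(nc);
    }
  }

  void update_anchors(int ic) {
    int na = 0;
    bool pl = false;
    for (int im : comp[ic].members) {
      if (tpl[mol[im].type].anchored) pl = true;
      for (size_t s = 0; s < mol[im].partner.size(); ++s)
        if (mol[im].partner[s] == -2) na++;
    }
    comp[ic].anchors = na;
    comp[ic].planar = pl;
    update_D(ic);
  }

  bool cycle_bond(int im, int s, int jm, int u) {
    unbind_sites(im, s, jm, u);
    std::vector<int> stack{im}, seen{im};
    bool connected = false;
    while (!stack.empty() && !connected) {
      int cur = stack.back(); stack.pop_back();
      const Molecule& mc = mol[cur];
      for (size_t ss = 0; ss < mc.partner.size(); ++ss) {
        if (mc.partner[ss] < 0) continue;
        int other = mc.partner[ss] / 64;
        if (other == jm) { connected = true; break; }
        if (std::find(seen.begin(), seen.end(), other) == seen.end()) {
          seen.push_back(other); stack.push_back(other);
        }
      }
    }
    bind_sites(im, s, jm, u);
    return connected;
  }

  // ------ binding ------------------------------------------------------------

  struct Event { int im, s, jm, u, k; double p; };
  std::vector<Event> ev, ring_ev;

  // complex of jm moves into the bound pose with im's site; on steric or
  // rotation-threshold failure everything is restored and false returned
  bool snap_pair(int im, int s, int jm, int u, double sigma) {
    Molecule& m1 = mol[im];
    Molecule& m2 = mol[jm];
    int ic1 = m1.comp, ic2 = m2.comp;
    Vec3 p1 = m1.sg[s];
    Vec3 d1 = p1 - m1.pos;
    double n1 = d1.norm();
    d1 = n1 > 1e-9 ? d1 * (1.0 / n1) : Vec3(0, 0, 1);
    Vec3 target = p1 + d1 * sigma;

    std::vector<int> sid; std::vector<Vec3> spos; std::vector<Quat> squat;
    save_pose(ic2, sid, spos, squat);

    // move m2's complex to the minimum image near m1 (a pure box-vector
    // translation; it must not count toward the rotation-displacement test)
    Vec3 dmi = mind(m2.pos, m1.pos);
    Vec3 shift_mi = (m1.pos + dmi) - m2.pos;
    if (shift_mi.norm() > 1e-9)
      for (int q : comp[ic2].members) {
        mol[q].pos = mol[q].pos + shift_mi; cache_sites(q);
      }
    std::vector<Vec3> ref_pos;
    for (int q : sid) ref_pos.push_back(mol[q].pos);

    Vec3 p2 = m2.sg[u];
    Vec3 d2 = p2 - m2.pos;
    double n2 = d2.norm();
    Quat rot;
    if (n2 > 1e-9) {
      d2 = d2 * (1.0 / n2);
      rot = quat_between(d2, d1 * (-1.0));
      Vec3 a2 = (rot * m2.q).rotate(Vec3(0, 0, 1));
      Vec3 a1 = m1.q.rotate(Vec3(0, 0, 1));
      Vec3 nrm = d1.cross(a1);
      if (nrm.norm() > 1e-9) {
        nrm = nrm * (1.0 / nrm.norm());
        Vec3 in_plane = nrm.cross(d1);
        double phi = std::atan2(a2.dot(nrm), a2.dot(in_plane));
        rot = quat_axis_angle(d1, -phi) * rot;
      }
    }
    move_complex(ic2, Vec3(), rot, m2.pos);
    double rd = 0;
    for (size_t a = 0; a < sid.size(); ++a)
      rd = std::max(rd, (mol[sid[a]].pos - ref_pos[a]).norm());
    if (rd > max_rot) {
      restore_pose(sid, spos, squat);
      n_rej_rot++;
      return false;
    }
    Vec3 tr = target - mol[jm].sg[u];
    for (int q : comp[ic2].members) {
      mol[q].pos = mol[q].pos + tr; cache_sites(q);
    }
    bool ok = true;
    if (on_mem(ic1) || on_mem(ic2)) {
      for (int q : comp[ic2].members)
        if (mol[q].pos.z < -1e-6) { ok = false; break; }
    }
    if (ok) {
      bind_sites(im, s, jm, u);
      merge_complexes(ic1, ic2);
      bool clash = internal_overlap(m1.comp);
      if (!clash)
        for (int q : comp[m1.comp].members)
          if (mol_overlaps(q)) { clash = true; break; }
      if (clash) {
        unbind_sites(im, s, jm, u);
        split_complex(m1.comp);
        restore_pose(sid, spos, squat);
        ok = false;
      }
    } else {
      restore_pose(sid, spos, squat);
    }
    if (!ok) n_rej_steric++;
    return ok;
  }

  bool attach_implicit(int im, int s) {
    Molecule& m = mol[im];
    int ic = m.comp;
    std::vector<int> sid; std::vector<Vec3> spos; std::vector<Quat> squat;
    save_pose(ic, sid, spos, squat);
    if (!on_mem(ic)) {
      Vec3 axis = m.q.rotate(Vec3(0, 0, 1));
      Quat rot = quat_between(axis, Vec3(0, 0, 1));
      move_complex(ic, Vec3(), rot, m.pos);
      double rd = 0;
      for (size_t a = 0; a < sid.size(); ++a)
        rd = std::max(rd, (mol[sid[a]].pos - spos[a]).norm());
      if (rd > max_rot) {
        restore_pose(sid, spos, squat);
        n_rej_rot++;
        return false;
      }
    }
    double dz = imp_site_z - m.sg[s].z;
    for (int q : comp[ic].members) { mol[q].pos.z += dz; cache_sites(q); }
    bool bad = false;
    for (int q : comp[ic].members) {
      if (mol[q].pos.z < -1e-6) { bad = true; break; }
      if (mol_overlaps(q)) { bad = true; break; }
    }
    if (bad) {
      restore_pose(sid, spos, squat);
      n_rej_steric++;
      return false;
    }
    m.partner[s] = -2;
    update_anchors(ic);
    return true;
  }

  Quat random_quat() {
    double u1 = unif_rand(), u2 = unif_rand(), u3 = unif_rand();
    double a = std::sqrt(1 - u1), b = std::sqrt(u1);
    return {a * std::sin(2 * M_PI * u2), a * std::cos(2 * M_PI * u2),
            b * std::sin(2 * M_PI * u3), b * std::cos(2 * M_PI * u3)};
  }

  // cached gf3d tables keyed on (channel, D quantized to 1e-3)
  struct PTab { int k; long dq; double fc; double r0, dr; std::vector<double> p; };
  std::vector<PTab> ptabs;
  double gf3d_cached(int k, double fc, double D, double r) {
    long dq = (long)(D * 1000 + 0.5);
    PTab* tab = nullptr;
    for (auto& t : ptabs)
      if (t.k == k && t.dq == dq && t.fc == fc) { tab = &t; break; }
    if (!tab) {
      PTab t;
      t.k = k; t.dq = dq; t.fc = fc;
      const Channel& K = chan[k];
      t.r0 = K.sigma;
      double rmax = K.sigma + 3.0 * std::sqrt(4.0 * D * dt);
      int n = 256;
      t.dr = (rmax - t.r0) / (n - 1);
      t.p.resize(n);
      for (int i = 0; i < n; ++i)
        t.p[i] = gf3d_prob(t.r0 + i * t.dr, K.ka3 * fc, D, K.sigma, dt);
      if (ptabs.size() > 512) ptabs.clear();  // bound the cache
      ptabs.push_back(std::move(t));
      tab = &ptabs.back();
    }
    if (r <= tab->r0) return tab->p[0];
    double x = (r - tab->r0) / tab->dr;
    int i = (int)x;
    if (i >= (int)tab->p.size() - 1) return 0.0;
    double f = x - i;
    return tab->p[i] * (1 - f) + tab->p[i + 1] * f;
  }

  double max_pair_D() const {
    double mx = 0;
    for (const Template& T : tpl)
      mx = std::max(mx, std::max(T.D.x, std::max(T.D.y, T.D.z)));
    return 2 * mx;
  }

  // ------ one time step ------------------------------------------------------

  void step() {
    for (auto& c : comp) c.reacted = false;
    tic();

    // (1) reservoir
    if (res_type >= 0 && res_kd > 0) {
      double pd = 1.0 - std::exp(-res_kd * dt);
      size_t nm0 = mol.size();
      for (size_t im = 0; im < nm0; ++im) {
        Molecule& m = mol[im];
        if (!m.alive || m.type != res_type) continue;
        const Complexo& c = comp[m.comp];
        if (c.members.size() != 1 || c.anchors > 0 || c.planar) continue;
        bool bonded = false;
        for (int p : m.partner) if (p != -1) { bonded = true; break; }
        if (bonded) continue;
        if (unif_rand() < pd) destroy_molecule((int)im);
      }
      int ncreate = (int)R::rpois(res_target * res_kd * dt);
      for (int n = 0; n < ncreate; ++n) {
        for (int tries = 0; tries < 50; ++tries) {
          Vec3 p{unif_rand() * Lx, unif_rand() * Ly, unif_rand() * Lz};
          int im = new_molecule(res_type, p, random_quat());
          if (cells[cell_of(p)].empty()) used_cells.push_back(cell_of(p));
          cells[cell_of(p)].push_back(im);
          if (!mol_overlaps(im)) break;
          auto& cc = cells[cell_of(p)];
          cc.erase(std::remove(cc.begin(), cc.end(), im), cc.end());
          destroy_molecule(im);
        }
      }
    }

    t_res += toc(); tic();
    // (2) dissociation of explicit bonds
    for (size_t im = 0; im < mol.size(); ++im) {
      if (!mol[im].alive) continue;
      Molecule& m = mol[im];
      const Template& T = tpl[m.type];
      for (int s = 0; s < T.nsite; ++s) {
        int code = m.partner[s];
        if (code < 0) continue;
        int jm = code / 64, u = code % 64;
        if (jm < (int)im) continue;  // evaluate each bond once
        int k = chan_of(T.cls[s], tpl[mol[jm].type].cls[u]);
        if (k < 0) continue;
        if (unif_rand() >= 1.0 - std::exp(-chan[k].kb * dt)) continue;
        bool cyc = cycle_bond((int)im, s, jm, u);
        unbind_sites((int)im, s, jm, u);
        n_events++;
        int ic = m.comp;
        comp[ic].reacted = true;
        if (!cyc) {
          split_complex(ic);
          int ici = m.comp, icj = mol[jm].comp;
          comp[icj].reacted = true;
          // detailed balance for the 2D reactive-annulus scheme: single
          // molecules re-placed uniformly in the annulus
          if (on_mem(ici) && on_mem(icj) &&
              comp[ici].members.size() == 1 &&
              comp[icj].members.size() == 1 && chan[k].ka2 >= 0) {
            double s0 = chan[k].sigma, s1 = chan[k].sigma + delta2d;
            double rr =
              std::sqrt(s0 * s0 + unif_rand() * (s1 * s1 - s0 * s0));
            double th = unif_rand() * 2 * M_PI;
            Vec3 off = mol[jm].sg[u] - mol[jm].pos;
            mol[jm].pos.x = m.sg[s].x + rr * std::cos(th) - off.x;
            mol[jm].pos.y = m.sg[s].y + rr * std::sin(th) - off.y;
            cache_sites(jm);
            wrap_complex(icj);
          }
        }
      }
    }

    // (2b) implicit-site unbinding
    if (n_imp_sites > 0 && imp_kb > 0) {
      double pq = 1.0 - std::exp(-imp_kb * dt);
      for (size_t im = 0; im < mol.size(); ++im) {
        Molecule& m = mol[im];
        if (!m.alive) continue;
        const Template& T = tpl[m.type];
        for (int s = 0; s < T.nsite; ++s) {
          if (m.partner[s] != -2 || T.cls[s] != imp_class) continue;
          if (unif_rand() >= pq) continue;
          m.partner[s] = -1;
          imp_occupied--;
          n_events++;
          int ic = m.comp;
          update_anchors(ic);
          comp[ic].reacted = true;
          if (!on_mem(ic) && comp[ic].members.size() == 1) {
            double znew = unif_rand() * imp_h;
            m.pos.z += znew - m.sg[s].z;
            cache_sites((int)im);
          }
        }
      }
    }

    t_dis += toc(); tic();
    // neighbor structure for binding, sterics and closure
    double reval = 0;
    for (const Channel& K : chan) reval = std::max(reval, K.sigma);
    reval += 3.0 * std::sqrt(4.0 * max_pair_D() * dt);
    scan_reval = reval;
    double maxext = 0;
    for (const Template& T : tpl) maxext = std::max(maxext, T.max_ext);
    build_cells(reval + 2 * maxext + 1.0);

    t_cells += toc(); tic();
    // (3a) implicit-site binding (3D -> 2D)
    if (n_imp_sites > 0 && imp_ka > 0) {
      double rho_free = (double)(n_imp_sites - imp_occupied) / (Lx * Ly);
      double pb = imp_ka * rho_free * dt / imp_h;
      if (pb > 0) {
        for (size_t im = 0; im < mol.size(); ++im) {
          Molecule& m = mol[im];
          if (!m.alive) continue;
          if (imp_occupied >= n_imp_sites) break;
          const Template& T = tpl[m.type];
          int ic = m.comp;
          for (int s = 0; s < T.nsite; ++s) {
            if (m.partner[s] != -1 || T.cls[s] != imp_class) continue;
            if (m.sg[s].z < 0 || m.sg[s].z >= imp_h) continue;
            if (unif_rand() >= pb) continue;
            if (!attach_implicit((int)im, s)) continue;
            imp_occupied++;
            comp[ic].reacted = true;
            n_events++;
            break;
          }
        }
      }
    }

    t_imp += toc(); tic();
    // (3b) pairwise binding between complexes; same-complex pairs become
    //      ring-closure attempts (strained, within the contact cutoff)
    ev.clear();
    ring_ev.clear();
    for (size_t im = 0; im < mol.size(); ++im) {
      const Molecule& m = mol[im];
      if (!m.alive || !has_free_rx((int)im)) continue;
      const Template& T = tpl[m.type];
      double scan_range = scan_reval + 2 * T.max_ext + 20;
      for_neighbors(m.pos, [&](int jm) {
        if (jm <= (int)im) return;
        const Molecule& o = mol[jm];
        if (!o.alive || !has_free_rx(jm)) return;
        Vec3 dcom = mind(m.pos, o.pos);
        if (dcom.dot(dcom) > scan_range * scan_range) return;
        const Template& To = tpl[o.type];
        bool same = o.comp == m.comp;
        for (int s = 0; s < T.nsite; ++s) {
          if (m.partner[s] != -1) continue;
          for (int u = 0; u < To.nsite; ++u) {
            if (o.partner[u] != -1) continue;
            int k = chan_of(T.cls[s], To.cls[u]);
            if (k < 0) continue;
            const Channel& K = chan[k];
            if (K.memonly && !same && !on_mem(m.comp) && !on_mem(o.comp))
              continue;
            double fc = 1.0;
            if (K.coop) {
              bool ai = adaptor_bound((int)im), aj = adaptor_bound(jm);
              if (coop_either ? (ai || aj) : (ai && aj)) fc = f_coop;
            }
            if (same) {
              // stride: attempt every ring_every steps with rescaled
              // probability (p << 1, so the compound process is unchanged)
              if (!K.ring || step_count % ring_every != 0) continue;
              Vec3 dr_ = mind(m.sg[s], o.sg[u]);
              if (dr_.norm() > ring_cutoff) continue;
              double c0_over_KD = 0.602214076 * (K.ka3 * fc) / K.kb;
              double pq =
                K.kb * dt * ring_every * c0_over_KD * exp_neg_strain;
              if (pq > 1) pq = 1;
              ring_ev.push_back({(int)im, s, jm, u, k, pq});
              continue;
            }
            Vec3 d = mind(m.sg[s], o.sg[u]);
            double p = 0;
            bool both2d = on_mem(m.comp) && on_mem(o.comp);
            if (both2d && K.ka2 >= 0) {
              double rxy = std::sqrt(d.x * d.x + d.y * d.y);
              if (rxy >= K.sigma && rxy < K.sigma + delta2d) {
                double s1 = K.sigma + delta2d;
                double Aann = M_PI * (s1 * s1 - K.sigma * K.sigma);
                p = 1.0 - std::exp(-K.ka2 * fc * dt / Aann);
              }
            } else {
              double Dtot =
                (comp[m.comp].D.x + comp[m.comp].D.y + comp[m.comp].D.z +
                 comp[o.comp].D.x + comp[o.comp].D.y + comp[o.comp].D.z) /
                3.0;
              if (Dtot <= 0) Dtot = 1e-6;
              double r = d.norm();
              if (r < K.sigma + 3.0 * std::sqrt(4.0 * Dtot * dt))
                p = gf3d_cached(k, fc, Dtot, r);
            }
            if (p > 0) ev.push_back({(int)im, s, jm, u, k, p});
          }
        }
      });
    }
    t_scan += toc(); tic();
    for (size_t a = ev.size(); a > 1; --a)
      std::swap(ev[a - 1], ev[(size_t)(unif_rand() * a)]);
    for (const Event& e : ev) {
      if (mol[e.im].partner[e.s] != -1 || mol[e.jm].partner[e.u] != -1)
        continue;
      if (mol[e.im].comp == mol[e.jm].comp) continue;
      if (unif_rand() >= e.p) continue;
      n_bind_accept++;
      int ic1 = mol[e.im].comp, ic2 = mol[e.jm].comp;
      int a = e.im, sa = e.s, b = e.jm, sb = e.u;
      bool on1 = on_mem(ic1), on2 = on_mem(ic2);
      if ((on2 && !on1) ||
          (on1 == on2 &&
           comp[ic1].members.size() < comp[ic2].members.size())) {
        std::swap(a, b); std::swap(sa, sb);
      }
      if (snap_pair(a, sa, b, sb, chan[e.k].sigma)) {
        comp[mol[a].comp].reacted = true;
        n_events++;
      } else {
        n_snap_fail++;
      }
    }
    for (const Event& e : ring_ev) {
      if (mol[e.im].partner[e.s] != -1 || mol[e.jm].partner[e.u] != -1)
        continue;
      if (mol[e.im].comp != mol[e.jm].comp) continue;  // fragmented meanwhile
      if (unif_rand() >= e.p) continue;
      bind_sites(e.im, e.s, e.jm, e.u);
      comp[mol[e.im].comp].reacted = true;
      n_events++;
    }

    t_apply += toc(); tic();
    // (4) diffusion with excluded-volume rejection
    for (size_t ic = 0; ic < comp.size(); ++ic) {
      Complexo& c = comp[ic];
      if (!c.alive || c.reacted) continue;
      // large membrane lattices diffuse negligibly; skip sub-resolution
      // moves (rms member displacement, incl. rotation x extent, < 0.3 nm)
      double dmax = std::max(c.D.x, std::max(c.D.y, c.D.z));
      double rmax = std::max(c.DR.x, std::max(c.DR.y, c.DR.z));
      double e2 = std::max(c.ext * c.ext, 1.0);
      if (2 * dmax * dt < 0.09 && 2 * rmax * dt * e2 < 0.09) continue;
      Vec3 cen = centroid((int)ic);
      sb_ids.assign(comp[ic].members.begin(), comp[ic].members.end());
      sb_pos.clear(); sb_quat.clear();
      for (int im : sb_ids) {
        sb_pos.push_back(mol[im].pos); sb_quat.push_back(mol[im].q);
      }
      // single proposal, reject-and-stay: resampling to acceptance would
      // deplete the pair density near contact and bias association rates
      for (int tries = 0; tries < 1; ++tries) {
        Vec3 dr{c.D.x > 0 ? std::sqrt(2 * c.D.x * dt) * norm_rand() : 0,
                c.D.y > 0 ? std::sqrt(2 * c.D.y * dt) * norm_rand() : 0,
                c.D.z > 0 ? std::sqrt(2 * c.D.z * dt) * norm_rand() : 0};
        Quat rot;
        if (c.DR.x > 0)
          rot = quat_axis_angle(Vec3(1, 0, 0),
                                std::sqrt(2 * c.DR.x * dt) * norm_rand());
        if (c.DR.y > 0)
          rot = quat_axis_angle(Vec3(0, 1, 0),
                                std::sqrt(2 * c.DR.y * dt) * norm_rand()) *
                rot;
        if (c.DR.z > 0)
          rot = quat_axis_angle(Vec3(0, 0, 1),
                                std::sqrt(2 * c.DR.z * dt) * norm_rand()) *
                rot;
        if (on_mem((int)ic)) {
          dr.z = 0;
        } else if (!periodic_z) {
          if (cen.z + dr.z < 0) dr.z = -2 * cen.z - dr.z;
          if (cen.z + dr.z > Lz) dr.z = 2 * (Lz - cen.z) - dr.z;
        }
        move_complex((int)ic, dr, rot, cen);
        bool bad = false;
        for (int im : c.members)
          if (mol_overlaps(im)) { bad = true; break; }
        if (!bad) { wrap_complex((int)ic); break; }
        restore_pose(sb_ids, sb_pos, sb_quat);
        n_rej_steric++;
      }
    }

    t_diff += toc();
    t += dt;
    step_count++;
  }
};

// ---------- R interface -------------------------------------------------------

static Sim build_sim(List cfg) {
  Sim S;
  NumericVector box = cfg["box_nm"];
  S.Lx = box[0]; S.Ly = box[1]; S.Lz = box[2];
  S.dt = as<double>(cfg["dt_us"]);
  S.periodic_z = as<bool>(cfg["periodic_z"]);
  S.delta2d = as<double>(cfg["delta2d_nm"]);
  S.max_rot = as<double>(cfg["max_rotation_nm"]);
  S.f_coop = as<double>(cfg["f_coop"]);
  S.coop_either = as<bool>(cfg["coop_either"]);
  S.ring_cutoff = as<double>(cfg["ring_cutoff_nm"]);
  S.exp_neg_strain = as<double>(cfg["exp_neg_strain"]);
  S.coop_marker_class = as<int>(cfg["coop_marker_class"]);

  List tls = cfg["templates"];
  for (int i = 0; i < tls.size(); ++i) {
    List tl = tls[i];
    Template T;
    NumericMatrix loc = tl["local"];
    T.nsite = loc.ncol();
    for (int s = 0; s < T.nsite; ++s) {
      Vec3 v{loc(0, s), loc(1, s), loc(2, s)};
      T.local.push_back(v);
      T.max_ext = std::max(T.max_ext, v.norm());
    }
    IntegerVector cl = tl["cls"];
    T.cls = std::vector<int>(cl.begin(), cl.end());
    NumericVector ex = tl["excl"];
    T.excl = std::vector<double>(ex.begin(), ex.end());
    T.com_excl = as<double>(tl["com_excl"]);
    NumericVector D = tl["D"], DR = tl["DR"];
    T.D = {D[0], D[1], D[2]}; T.DR = {DR[0], DR[1], DR[2]};
    T.anchored = as<bool>(tl["anchored"]);
    S.tpl.push_back(T);
  }

  List chs = cfg["channels"];
  for (int i = 0; i < chs.size(); ++i) {
    List ch = chs[i];
    Channel K;
    K.c1 = as<int>(ch["c1"]); K.c2 = as<int>(ch["c2"]);
    K.ka3 = as<double>(ch["ka3"]); K.ka2 = as<double>(ch["ka2"]);
    K.kb = as<double>(ch["kb"]); K.sigma = as<double>(ch["sigma"]);
    K.coop = as<bool>(ch["coop"]); K.ring = as<bool>(ch["ring"]);
    K.memonly = as<bool>(ch["memonly"]);
    S.chan.push_back(K);
  }

  S.build_chan_lut();
  S.build_steric_range();

  S.n_imp_sites = (long)as<double>(cfg["n_implicit_sites"]);
  S.imp_class = as<int>(cfg["implicit_class"]);
  S.imp_ka = as<double>(cfg["implicit_ka"]);
  S.imp_kb = as<double>(cfg["implicit_kb"]);
  S.imp_h = as<double>(cfg["implicit_h_nm"]);
  S.imp_site_z = as<double>(cfg["implicit_site_z_nm"]);
  S.res_type = as<int>(cfg["reservoir_type"]);
  S.res_target = as<double>(cfg["reservoir_target"]);
  S.res_kd = as<double>(cfg["reservoir_kdestroy_us"]);

  IntegerVector ity = cfg["init_type"];
  NumericMatrix ipos = cfg["init_pos"];
  S.build_cells(60.0);
  for (int i = 0; i < ity.size(); ++i) {
    Vec3 p{ipos(0, i), ipos(1, i), ipos(2, i)};
    int im = S.new_molecule(ity[i], p, S.random_quat());
    if (S.cells[S.cell_of(p)].empty())
      S.used_cells.push_back(S.cell_of(p));
    S.cells[S.cell_of(p)].push_back(im);
    int tries = 0;
    while (S.mol_overlaps(im) && tries++ < 200) {
      std::vector<int>& oc = S.cells[S.cell_of(S.mol[im].pos)];
      oc.erase(std::remove(oc.begin(), oc.end(), im), oc.end());
      S.mol[im].pos = {unif_rand() * S.Lx, unif_rand() * S.Ly,
                       unif_rand() * S.Lz};
      S.cache_sites(im);
      int nc2 = S.cell_of(S.mol[im].pos);
      if (S.cells[nc2].empty()) S.used_cells.push_back(nc2);
      S.cells[nc2].push_back(im);
    }
  }
  return S;
}

// [[Rcpp::export]]
List debug_propensity(List cfg) {
  Sim S = build_sim(cfg);
  double sum_cells = 0, sum_brute = 0;
  // brute force over all alive pairs
  for (size_t im = 0; im < S.mol.size(); ++im) {
    if (!S.mol[im].alive) continue;
    const Template& T = S.tpl[S.mol[im].type];
    for (size_t jm = im + 1; jm < S.mol.size(); ++jm) {
      if (!S.mol[jm].alive) continue;
      const Template& To = S.tpl[S.mol[jm].type];
      for (int ss = 0; ss < T.nsite; ++ss)
        for (int u = 0; u < To.nsite; ++u) {
          int k = S.chan_of(T.cls[ss], To.cls[u]);
          if (k < 0) continue;
          const Channel& K = S.chan[k];
          Vec3 d = S.mind(S.mol[im].sg[ss], S.mol[jm].sg[u]);
          double Dtot = (S.comp[S.mol[im].comp].D.x * 3 +
                         S.comp[S.mol[jm].comp].D.x * 3) / 3.0;
          sum_brute += gf3d_prob(d.norm(), K.ka3, Dtot, K.sigma, S.dt);
        }
    }
  }
  // via the cell enumeration (mirror of the binding loop)
  double reval = 0;
  for (const Channel& K : S.chan) reval = std::max(reval, K.sigma);
  reval += 3.0 * std::sqrt(4.0 * S.max_pair_D() * S.dt);
  double maxext = 0;
  for (const Template& T : S.tpl) maxext = std::max(maxext, T.max_ext);
  S.build_cells(reval + 2 * maxext + 1.0);
  for (size_t im = 0; im < S.mol.size(); ++im) {
    const Molecule& m = S.mol[im];
    if (!m.alive) continue;
    const Template& T = S.tpl[m.type];
    S.for_neighbors(m.pos, [&](int jm) {
      if (jm <= (int)im) return;
      const Molecule& o = S.mol[jm];
      if (!o.alive || o.comp == m.comp) return;
      const Template& To = S.tpl[o.type];
      for (int ss = 0; ss < T.nsite; ++ss)
        for (int u = 0; u < To.nsite; ++u) {
          int k = S.chan_of(T.cls[ss], To.cls[u]);
          if (k < 0) continue;
          const Channel& K = S.chan[k];
          Vec3 d = S.mind(m.sg[ss], o.sg[u]);
          double Dtot =
            (S.comp[m.comp].D.x + S.comp[m.comp].D.y + S.comp[m.comp].D.z +
             S.comp[o.comp].D.x + S.comp[o.comp].D.y + S.comp[o.comp].D.z) /
            3.0;
          double r = d.norm();
          if (r < K.sigma + 3.0 * std::sqrt(4.0 * Dtot * S.dt))
            sum_cells += S.gf3d_cached(k, 1.0, Dtot, r);
        }
    });
  }
  return List::create(_["sum_brute"] = sum_brute,
                      _["sum_cells"] = sum_cells);
}

// [[Rcpp::export]]
List simulate_core(List cfg, int n_steps, int output_every) {
  Sim S = build_sim(cfg);
  int census_type = as<int>(cfg["census_type"]);

  std::vector<double> f_time, f_mem0, f_sol0, f_mem1, f_sol1, f_bonds;
  std::vector<std::vector<int>> f_sizes;

  auto record = [&]() {
    f_time.push_back(S.t * 1e-6);
    double mem0 = 0, sol0 = 0, mem1 = 0, sol1 = 0, nb = 0;
    std::vector<int> sizes;
    for (size_t ic = 0; ic < S.comp.size(); ++ic) {
      const Complexo& c = S.comp[ic];
      if (!c.alive) continue;
      bool onmem = c.anchors > 0 || c.planar;
      int ncl = 0;
      for (int im : c.members) {
        const Molecule& m = S.mol[im];
        if (m.type == census_type) ncl++;
        if (m.type == 0) { if (onmem) mem0++; else sol0++; }
        else if (m.type == 1) { if (onmem) mem1++; else sol1++; }
        for (int p : m.partner) if (p >= 0) nb += 0.5;
      }
      if (ncl > 0) sizes.push_back(ncl);
    }
    f_mem0.push_back(mem0); f_sol0.push_back(sol0);
    f_mem1.push_back(mem1); f_sol1.push_back(sol1);
    f_bonds.push_back(nb);
    f_sizes.push_back(sizes);
  };

  record();
  for (int i = 1; i <= n_steps; ++i) {
    S.step();
    if (i % output_every == 0) record();
    if (i % 5000 == 0) Rcpp::checkUserInterrupt();
  }

  int nAlive = 0;
  for (const Molecule& m : S.mol) if (m.alive) nAlive++;
  NumericMatrix fpos(3, nAlive);
  NumericMatrix fquat(4, nAlive);
  IntegerVector ftype(nAlive), fcomp(nAlive);
  int idx = 0;
  for (const Molecule& m : S.mol) {
    if (!m.alive) continue;
    fpos(0, idx) = m.pos.x; fpos(1, idx) = m.pos.y; fpos(2, idx) = m.pos.z;
    fquat(0, idx) = m.q.w; fquat(1, idx) = m.q.x;
    fquat(2, idx) = m.q.y; fquat(3, idx) = m.q.z;
    ftype[idx] = m.type;
    fcomp[idx] = m.comp;
    idx++;
  }

  List sizes(f_sizes.size());
  for (size_t i = 0; i < f_sizes.size(); ++i)
    sizes[i] = IntegerVector(f_sizes[i].begin(), f_sizes[i].end());

  return List::create(
    _["time_s"] = f_time,
    _["mem_type0"] = f_mem0, _["sol_type0"] = f_sol0,
    _["mem_type1"] = f_mem1, _["sol_type1"] = f_sol1,
    _["n_bonds"] = f_bonds,
    _["cluster_sizes"] = sizes,
    _["final_type"] = ftype, _["final_comp"] = fcomp,
    _["final_pos"] = fpos, _["final_quat"] = fquat,
    _["implicit_occupied"] = (double)S.imp_occupied,
    _["n_events"] = S.n_events,
    _["n_rej_steric"] = S.n_rej_steric,
    _["n_rej_rot"] = S.n_rej_rot,
    _["n_bind_accept"] = S.n_bind_accept,
    _["n_snap_fail"] = S.n_snap_fail,
    _["prof"] = NumericVector::create(S.t_res, S.t_dis, S.t_cells, S.t_imp,
                                      S.t_scan, S.t_apply, S.t_diff));
}
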