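// Next-particle-method event engine on a hierarchy of nested Cartesian
// meshes. Molecules are individual particles with a (level, voxel)
// position; tentative diffusion / unimolecular / bimolecular / birth
// events live on one global binary heap and are executed in time order.
// Invalidated events (a reactant died, or a partner moved) are discarded
// lazily at pop time via liveness flags and per-molecule version stamps.

#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

enum EvKind { EV_DIFF = 0, EV_UNI = 1, EV_BI = 2, EV_BIRTH = 3 };

struct Event {
  double time;
  int64_t seq;     // insertion order, deterministic tie-break
  int kind;
  int ch;          // channel index (-1 for diffusion)
  int a1, a2;      // molecule uids (-1 unused)
  int64_t v1, v2;  // bimolecular version stamps of the actors
};

struct EventCmp {
  bool operator()(const Event& a, const Event& b) const {
    if (a.time != b.time) return a.time > b.time;
    return a.seq > b.seq;
  }
};

struct Engine {
  // ---- model ----
  int nSpecies = 0, nLevels = 0, nChannels = 0;
  double side = 1.0;
  std::vector<double> D;                    // per species
  std::vector<int> bornLevel;               // per species finest level
  std::vector<int> order, re1, re2;         // per channel
  std::vector<std::vector<int>> products;   // per channel
  std::vector<double> kmicro;               // per channel
  std::vector<std::vector<double>> kmeso;   // [channel][level], order 2
  std::vector<double> h;                    // per level voxel width
  std::vector<int> nside;                   // per level voxels per axis
  std::vector<std::vector<double>> faceRate;  // [species][level] D/h^2
  std::vector<std::vector<double>> tTransfer; // [species][level]
  bool transfersEnabled = true;

  std::vector<std::vector<int>> uniCh;  // per species: uni channels
  // per species: (bi channel, partner species)
  std::vector<std::vector<std::pair<int, int>>> biCh;

  // ---- state ----
  std::vector<int> mSpec, mLev, mX, mY, mZ;
  std::vector<double> mTLast;   // time of last transfer or birth
  std::vector<char> mAlive;
  std::vector<int64_t> mBiver;  // invalidates pending bi events on move
  // reg[l]: voxel key -> uids of molecules at levels >= l whose ancestor
  // voxel at level l is that voxel (molecules register on levels 0..lev)
  std::vector<std::unordered_map<int64_t, std::vector<int>>> reg;
  std::vector<std::vector<int>> atLevel;  // [level][species] counts
  std::vector<int> counts;                // per species copy numbers
  std::priority_queue<Event, std::vector<Event>, EventCmp> q;
  int64_t seq = 0;
  double now = 0.0;
  double nEvents = 0;  // executed events (double: may exceed 2^31)
  int64_t initEvents[4] = {0, 0, 0, 0};

  // ---- logging ----
  bool logReactions = false, logTransfers = false;
  std::vector<double> rTime;
  std::vector<int> rKind, rCh, rA1, rA2, rP1, rP2, rP1lev, rP1vox,
      rP2lev, rP2vox;
  std::vector<double> tfTime;
  std::vector<int> tfUid, tfFrom, tfTo, tfFromVox, tfToVox;

  // ---- helpers ----
  int64_t key(int l, int x, int y, int z) const {
    int64_t n = nside[l];
    return (static_cast<int64_t>(z) * n + y) * n + x;
  }

  void regAdd(int l, int64_t k, int uid) { reg[l][k].push_back(uid); }

  void regRemove(int l, int64_t k, int uid) {
    auto it = reg[l].find(k);
    std::vector<int>& v = it->second;
    for (size_t i = 0; i < v.size(); ++i)
      if (v[i] == uid) { v[i] = v.back(); v.pop_back(); break; }
    if (v.empty()) reg[l].erase(it);
  }

  int uniformInt(int n) {  // uniform on {0, ..., n-1}
    int k = static_cast<int>(unif_rand() * n);
    return k >= n ? n - 1 : k;
  }

  void push(double time, int kind, int ch, int a1, int a2, int64_t v1,
            int64_t v2) {
    q.push(Event{time, seq++, kind, ch, a1, a2, v1, v2});
  }

  void sampleDiffusion(int m) {
    int l = mLev[m];
    if (l == 0) return;
    double fr = faceRate[mSpec[m]][l];
    if (fr <= 0) return;
    int n = nside[l], nb = 0;
    nb += (mX[m] > 0) + (mX[m] < n - 1);
    nb += (mY[m] > 0) + (mY[m] < n - 1);
    nb += (mZ[m] > 0) + (mZ[m] < n - 1);
    push(now + exp_rand() / (nb * fr), EV_DIFF, -1, m, -1, 0, 0);
  }

  void sampleUni(int m) {
    const std::vector<int>& chs = uniCh[mSpec[m]];
    if (chs.empty()) return;
    double tot = 0;
    for (int c : chs) tot += kmicro[c];
    if (tot <= 0) return;
    double u = unif_rand() * tot, acc = 0;
    int pick = chs.back();
    for (int c : chs) { acc += kmicro[c]; if (u <= acc) { pick = c; break; } }
    push(now + exp_rand() / tot, EV_UNI, pick, m, -1, 0, 0);
  }

  void schedulePair(int m1, int m2, int ch, int level) {
    double rate = kmeso[ch][level];
    if (rate <= 0) return;
    push(now + exp_rand() / rate, EV_BI, ch, m1, m2, mBiver[m1], mBiver[m2]);
  }

  // one tentative event per co-located (pair, channel); partners are
  // molecules in the same voxel on the same level, finer molecules inside
  // this voxel, or coarser molecules whose voxel contains this one; the
  // pair reacts at the rate of the coarser of the two levels
  void scanPairs(int m) {
    int sp = mSpec[m], l = mLev[m];
    for (const auto& cp : biCh[sp]) {
      int ch = cp.first, ps = cp.second;
      bool anyFine = false;
      for (int l2 = l; l2 < nLevels && !anyFine; ++l2)
        if (atLevel[l2][ps] > 0) anyFine = true;
      if (anyFine) {
        auto it = reg[l].find(key(l, mX[m], mY[m], mZ[m]));
        if (it != reg[l].end())
          for (int uid : it->second)
            if (uid != m && mAlive[uid] && mSpec[uid] == ps)
              schedulePair(m, uid, ch, l);
      }
      for (int l2 = 0; l2 < l; ++l2) {
        if (atLevel[l2][ps] == 0) continue;
        int sh = l - l2;
        auto it = reg[l2].find(key(l2, mX[m] >> sh, mY[m] >> sh,
                                   mZ[m] >> sh));
        if (it == reg[l2].end()) continue;
        for (int uid : it->second)
          if (uid != m && mAlive[uid] && mLev[uid] == l2 &&
              mSpec[uid] == ps)
            schedulePair(m, uid, ch, l2);
      }
    }
  }

  int addMolecule(int sp, int l, int x, int y, int z, int64_t* evCount) {
    int uid = static_cast<int>(mSpec.size());
    mSpec.push_back(sp); mLev.push_back(l);
    mX.push_back(x); mY.push_back(y); mZ.push_back(z);
    mTLast.push_back(now); mAlive.push_back(1); mBiver.push_back(0);
    counts[sp]++; atLevel[l][sp]++;
    for (int l2 = 0; l2 <= l; ++l2) {
      int sh = l - l2;
      regAdd(l2, key(l2, x >> sh, y >> sh, z >> sh), uid);
    }
    int64_t before = seq;
    sampleDiffusion(uid);
    if (evCount) evCount[EV_DIFF] += seq - before;
    before = seq;
    sampleUni(uid);
    if (evCount) evCount[EV_UNI] += seq - before;
    before = seq;
    scanPairs(uid);
    if (evCount) evCount[EV_BI] += seq - before;
    return uid;
  }

  void killMolecule(int m) {
    mAlive[m] = 0;
    counts[mSpec[m]]--;
    atLevel[mLev[m]][mSpec[m]]--;
    int l = mLev[m];
    for (int l2 = 0; l2 <= l; ++l2) {
      int sh = l - l2;
      regRemove(l2, key(l2, mX[m] >> sh, mY[m] >> sh, mZ[m] >> sh), m);
    }
  }

  // same-level move: update registry entries only on levels where the
  // ancestor voxel actually changes (once equal, all coarser levels match)
  void relocate(int m, int nx, int ny, int nz) {
    int l = mLev[m];
    for (int l2 = l; l2 >= 0; --l2) {
      int sh = l - l2;
      int64_t ok = key(l2, mX[m] >> sh, mY[m] >> sh, mZ[m] >> sh);
      int64_t nk = key(l2, nx >> sh, ny >> sh, nz >> sh);
      if (ok == nk) break;
      regRemove(l2, ok, m);
      regAdd(l2, nk, m);
    }
    mX[m] = nx; mY[m] = ny; mZ[m] = nz;
  }

  // promote to the parent voxel while the diffusion clock has run past
  // the transfer time of the current level; called only right after a
  // diffusion event, before events are resampled
  void maybePromote(int m) {
    if (!transfersEnabled) return;
    int sp = mSpec[m];
    while (mLev[m] > 0 && now - mTLast[m] >= tTransfer[sp][mLev[m]]) {
      int l = mLev[m];
      int64_t fromKey = key(l, mX[m], mY[m], mZ[m]);
      // registrations on levels 0..l-1 already point at the ancestors;
      // only the own-level entry disappears
      regRemove(l, fromKey, m);
      atLevel[l][sp]--;
      mLev[m] = l - 1;
      mX[m] >>= 1; mY[m] >>= 1; mZ[m] >>= 1;
      atLevel[l - 1][sp]++;
      mTLast[m] = now;
      if (logTransfers) {
        tfTime.push_back(now); tfUid.push_back(m);
        tfFrom.push_back(l); tfTo.push_back(l - 1);
        tfFromVox.push_back(static_cast<int>(fromKey));
        tfToVox.push_back(static_cast<int>(key(l - 1, mX[m], mY[m], mZ[m])));
      }
    }
  }

  // place products of channel ch relative to a reactant voxel; both
  // products of a dissociation that target the same level share one
  // sampled voxel, otherwise each product is placed independently:
  // coarser targets take the ancestor voxel, finer targets a uniformly
  // sampled descendant (iterated uniform child choice)
  void voxelFor(int targetLev, int rl, int rx, int ry, int rz, int* out) {
    int x = rx, y = ry, z = rz;
    if (targetLev <= rl) {
      int sh = rl - targetLev;
      x >>= sh; y >>= sh; z >>= sh;
    } else {
      for (int k = rl; k < targetLev; ++k) {
        int c = uniformInt(8);
        x = 2 * x + (c & 1); y = 2 * y + ((c >> 1) & 1);
        z = 2 * z + ((c >> 2) & 1);
      }
    }
    out[0] = x; out[1] = y; out[2] = z;
  }

  void placeProducts(int ch, int rl, int rx, int ry, int rz,
                     int* pu, int* plev, int* pvox) {
    const std::vector<int>& ps = products[ch];
    pu[0] = pu[1] = -1; plev[0] = plev[1] = -1; pvox[0] = pvox[1] = -1;
    if (ps.empty()) return;
    bool shared = ps.size() == 2 && bornLevel[ps[0]] == bornLevel[ps[1]];
    int v[3];
    if (shared) voxelFor(bornLevel[ps[0]], rl, rx, ry, rz, v);
    for (size_t i = 0; i < ps.size(); ++i) {
      int tl = bornLevel[ps[i]];
      if (!shared) voxelFor(tl, rl, rx, ry, rz, v);
      int uid = addMolecule(ps[i], tl, v[0], v[1], v[2], nullptr);
      if (i < 2) {
        pu[i] = uid; plev[i] = tl;
        pvox[i] = static_cast<int>(key(tl, v[0], v[1], v[2]));
      }
    }
  }

  void logReaction(int kind, int ch, int a1, int a2, const int* pu,
                   const int* plev, const int* pvox) {
    rTime.push_back(now); rKind.push_back(kind); rCh.push_back(ch + 1);
    rA1.push_back(a1); rA2.push_back(a2);
    rP1.push_back(pu[0]); rP2.push_back(pu[1]);
    rP1lev.push_back(plev[0]); rP1vox.push_back(pvox[0]);
    rP2lev.push_back(plev[1]); rP2vox.push_back(pvox[1]);
  }
};

}  // namespace

// [[Rcpp::export(name = ".npmRun")]]
List npmRun(List model, List control) {
  Engine E;

  // ---- unpack model ----
  E.nSpecies = as<int>(model["nSpecies"]);
  E.nLevels = as<int>(model["nLevels"]);
  E.side = as<double>(model["side"]);
  E.D = as<std::vector<double>>(model["D"]);
  E.bornLevel = as<std::vector<int>>(model["bornLevel"]);
  E.order = as<std::vector<int>>(model["order"]);
  E.re1 = as<std::vector<int>>(model["re1"]);
  E.re2 = as<std::vector<int>>(model["re2"]);
  E.kmicro = as<std::vector<double>>(model["kMicro"]);
  List prod = model["products"];
  E.nChannels = prod.size();
  for (int c = 0; c < E.nChannels; ++c)
    E.products.push_back(as<std::vector<int>>(prod[c]));
  NumericMatrix km = model["kMeso"];  // nChannels x nLevels
  E.kmeso.assign(E.nChannels, std::vector<double>(E.nLevels, 0.0));
  for (int c = 0; c < E.nChannels; ++c)
    for (int l = 0; l < E.nLevels; ++l) E.kmeso[c][l] = km(c, l);
  double C = as<double>(model["C"]);
  E.transfersEnabled = R_finite(C);

  E.h.resize(E.nLevels); E.nside.resize(E.nLevels);
  for (int l = 0; l < E.nLevels; ++l) {
    E.nside[l] = 1 << l;
    E.h[l] = E.side / E.nside[l];
  }
  E.faceRate.assign(E.nSpecies, std::vector<double>(E.nLevels, 0.0));
  E.tTransfer.assign(E.nSpecies,
                     std::vector<double>(E.nLevels, R_PosInf));
  for (int s = 0; s < E.nSpecies; ++s)
    for (int l = 0; l < E.nLevels; ++l) {
      E.faceRate[s][l] = E.D[s] / (E.h[l] * E.h[l]);
      if (E.D[s] > 0 && E.transfersEnabled)
        E.tTransfer[s][l] = (C * E.h[l]) * (C * E.h[l]) / (6.0 * E.D[s]);
    }

  E.uniCh.assign(E.nSpecies, {});
  E.biCh.assign(E.nSpecies, {});
  for (int c = 0; c < E.nChannels; ++c) {
    if (E.order[c] == 1) {
      E.uniCh[E.re1[c]].push_back(c);
    } else if (E.order[c] == 2) {
      E.biCh[E.re1[c]].push_back({c, E.re2[c]});
      if (E.re2[c] != E.re1[c]) E.biCh[E.re2[c]].push_back({c, E.re1[c]});
    }
  }

  // ---- unpack control ----
  double tFinal = as<double>(control["tFinal"]);
  std::vector<double> sTimes =
      as<std::vector<double>>(control["sampleTimes"]);
  int stopChannel = as<int>(control["stopChannel"]);  // -1 disables
  double stopCount = as<double>(control["stopCount"]);
  E.logReactions = as<bool>(control["recordReactions"]);
  E.logTransfers = as<bool>(control["recordTransfers"]);
  double maxEvents = as<double>(control["maxEvents"]);

  E.reg.assign(E.nLevels, {});
  E.atLevel.assign(E.nLevels, std::vector<int>(E.nSpecies, 0));
  E.counts.assign(E.nSpecies, 0);

  // ---- initial molecules (placement sampled R-side) ----
  IntegerMatrix init = model["init"];  // columns: species, level, x, y, z
  for (int i = 0; i < init.nrow(); ++i)
    E.addMolecule(init(i, 0), init(i, 1), init(i, 2), init(i, 3),
                  init(i, 4), E.initEvents);
  for (int c = 0; c < E.nChannels; ++c)
    if (E.order[c] == 0 && E.kmicro[c] > 0) {
      E.push(E.now + exp_rand() / E.kmicro[c], EV_BIRTH, c, -1, -1, 0, 0);
      E.initEvents[EV_BIRTH]++;
    }

  // ---- event loop ----
  size_t nS = sTimes.size(), si = 0;
  IntegerMatrix outCounts(nS, E.nSpecies);
  double fired = 0;  // firings of the stop channel
  bool done = false;
  int pu[2], plev[2], pvox[2];

  while (!done) {
    if (E.q.empty()) break;
    Event ev = E.q.top();
    if (ev.time > tFinal) break;
    E.q.pop();

    switch (ev.kind) {  // lazy validity checks
      case EV_DIFF:
      case EV_UNI:
        if (!E.mAlive[ev.a1]) continue;
        break;
      case EV_BI:
        if (!E.mAlive[ev.a1] || !E.mAlive[ev.a2] ||
            E.mBiver[ev.a1] != ev.v1 || E.mBiver[ev.a2] != ev.v2)
          continue;
        break;
      default: break;
    }

    while (si < nS && sTimes[si] < ev.time) {
      for (int s = 0; s < E.nSpecies; ++s) outCounts(si, s) = E.counts[s];
      ++si;
    }
    E.now = ev.time;
    E.nEvents += 1;
    if (E.nEvents > maxEvents)
      stop("event budget exceeded (maxEvents = %g)", maxEvents);
    if (((int64_t)E.nEvents & 0xFFFFF) == 0) checkUserInterrupt();

    switch (ev.kind) {
      case EV_DIFF: {
        int m = ev.a1;
        int n = E.nside[E.mLev[m]];
        int dirs[6][3], nb = 0;
        if (E.mX[m] > 0)     { dirs[nb][0] = -1; dirs[nb][1] = 0; dirs[nb][2] = 0; ++nb; }
        if (E.mX[m] < n - 1) { dirs[nb][0] = 1;  dirs[nb][1] = 0; dirs[nb][2] = 0; ++nb; }
        if (E.mY[m] > 0)     { dirs[nb][0] = 0; dirs[nb][1] = -1; dirs[nb][2] = 0; ++nb; }
        if (E.mY[m] < n - 1) { dirs[nb][0] = 0; dirs[nb][1] = 1;  dirs[nb][2] = 0; ++nb; }
        if (E.mZ[m] > 0)     { dirs[nb][0] = 0; dirs[nb][1] = 0; dirs[nb][2] = -1; ++nb; }
        if (E.mZ[m] < n - 1) { dirs[nb][0] = 0; dirs[nb][1] = 0; dirs[nb][2] = 1;  ++nb; }
        if (nb > 0) {
          int j = E.uniformInt(nb);
          E.relocate(m, E.mX[m] + dirs[j][0], E.mY[m] + dirs[j][1],
                     E.mZ[m] + dirs[j][2]);
        }
        E.maybePromote(m);
        E.mBiver[m]++;          // drop pending bimolecular events
        E.scanPairs(m);
        E.sampleDiffusion(m);
        break;
      }
      case EV_UNI: {
        int m = ev.a1, ch = ev.ch;
        int rl = E.mLev[m], rx = E.mX[m], ry = E.mY[m], rz = E.mZ[m];
        E.killMolecule(m);
        E.placeProducts(ch, rl, rx, ry, rz, pu, plev, pvox);
        if (E.logReactions) E.logReaction(EV_UNI, ch, m, -1, pu, plev, pvox);
        break;
      }
      case EV_BI: {
        int m1 = ev.a1, m2 = ev.a2, ch = ev.ch;
        // product placement anchored at the finer reactant's voxel
        int mf = (E.mLev[m2] > E.mLev[m1]) ? m2 : m1;
        int rl = E.mLev[mf], rx = E.mX[mf], ry = E.mY[mf], rz = E.mZ[mf];
        E.killMolecule(m1);
        E.killMolecule(m2);
        E.placeProducts(ch, rl, rx, ry, rz, pu, plev, pvox);
        if (E.logReactions) E.logReaction(EV_BI, ch, m1, m2, pu, plev, pvox);
        if (ch == stopChannel && ++fired >= stopCount) done = true;
        break;
      }
      case EV_BIRTH: {
        int ch = ev.ch;
        pu[0] = pu[1] = -1; plev[0] = plev[1] = -1; pvox[0] = pvox[1] = -1;
        for (size_t i = 0; i < E.products[ch].size(); ++i) {
          int sp = E.products[ch][i], l = E.bornLevel[sp];
          int n = E.nside[l];
          int x = E.uniformInt(n), y = E.uniformInt(n), z = E.uniformInt(n);
          int uid = E.addMolecule(sp, l, x, y, z, nullptr);
          if (i < 2) {
            pu[i] = uid; plev[i] = l;
            pvox[i] = static_cast<int>(E.key(l, x, y, z));
          }
        }
        if (E.logReactions)
          E.logReaction(EV_BIRTH, ch, -1, -1, pu, plev, pvox);
        E.push(E.now + exp_rand() / E.kmicro[ch], EV_BIRTH, ch, -1, -1,
               0, 0);
        break;
      }
    }
  }

  // flush remaining sample points with the final state
  for (; si < nS; ++si)
    for (int s = 0; s < E.nSpecies; ++s) outCounts(si, s) = E.counts[s];

  // final molecule states
  int nAlive = 0;
  for (char a : E.mAlive) nAlive += a;
  IntegerMatrix fin(nAlive, 6);
  NumericVector finT(nAlive);
  int r = 0;
  for (size_t m = 0; m < E.mAlive.size(); ++m)
    if (E.mAlive[m]) {
      fin(r, 0) = static_cast<int>(m); fin(r, 1) = E.mSpec[m];
      fin(r, 2) = E.mLev[m]; fin(r, 3) = E.mX[m]; fin(r, 4) = E.mY[m];
      fin(r, 5) = E.mZ[m];
      finT[r] = E.now - E.mTLast[m];
      ++r;
    }

  return List::create(
      _["counts"] = outCounts,
      _["finalTime"] = E.now,
      _["nEvents"] = E.nEvents,
      _["initEvents"] = IntegerVector::create(
          (int)E.initEvents[0], (int)E.initEvents[1], (int)E.initEvents[2],
          (int)E.initEvents[3]),
      _["reactions"] = List::create(
          _["time"] = wrap(E.rTime), _["kind"] = wrap(E.rKind),
          _["channel"] = wrap(E.rCh), _["a1"] = wrap(E.rA1),
          _["a2"] = wrap(E.rA2), _["p1"] = wrap(E.rP1),
          _["p2"] = wrap(E.rP2), _["p1Level"] = wrap(E.rP1lev),
          _["p1Voxel"] = wrap(E.rP1vox), _["p2Level"] = wrap(E.rP2lev),
          _["p2Voxel"] = wrap(E.rP2vox)),
      _["transfers"] = List::create(
          _["time"] = wrap(E.tfTime), _["uid"] = wrap(E.tfUid),
          _["fromLevel"] = wrap(E.tfFrom), _["toLevel"] = wrap(E.tfTo),
          _["fromVoxel"] = wrap(E.tfFromVox),
          _["toVoxel"] = wrap(E.tfToVox)),
      _["finalState"] = List::create(
          _["state"] = fin, _["tSinceTransfer"] = finT));
}
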