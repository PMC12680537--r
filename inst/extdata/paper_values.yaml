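# Headline values of the published global biomass-movement synthesis,
# bundled as editable inputs. Units are stated per entry; movement is
# Gt km yr^-1 unless noted. Provenance strings name the figure/table of
# the source synthesis each value was printed in.
groups:
  wild_land_mammals:
    movement: {value: 30, low: 10, high: 70, bound: 150, units: Gt km yr-1,
               provenance: "synthesis Results + Fig. 1b, wild land mammals excl. bats"}
    biomass: {value: 2.0e+7, low: 1.3e+7, high: 3.8e+7, units: t,
              provenance: "synthesis Results, combined biomass 20 Mt (13-38)"}
  land_arthropods:
    movement: {value: 30, low: 10, high: 90, bound: 300, units: Gt km yr-1,
               provenance: "synthesis Fig. 1b, terrestrial arthropods (range from extrema)"}
    biomass: {value: 1.0e+9, units: t,
              provenance: "synthesis Results, ~300x bird biomass"}
  wild_birds:
    movement: {value: 40, low: 15, high: 90, bound: 130, units: Gt km yr-1,
               provenance: "synthesis Results + Fig. 1b, all wild birds"}
    biomass: {value: 3.0e+6, units: t, provenance: "synthesis Results, ~3 Mt"}
  terrestrial_animals_combined:
    movement: {value: 100, high: 400, bound: 700, units: Gt km yr-1,
               provenance: "synthesis Results, ~100 with upper estimate ~400 and bound ~700"}
  flying_wild_animals:
    movement: {value: 40, bound: 300, units: Gt km yr-1,
               provenance: "synthesis Results, in-air comparison"}
  livestock:
    movement: {value: 1000, low: 400, high: 1600, units: Gt km yr-1,
               provenance: "synthesis Results, 1,000 +/- 600"}
humans:
  population: {value: 8.0e+9, units: individuals, provenance: "synthesis Results"}
  body_mass_kg: {value: 54, units: kg, provenance: "synthesis Results, average ~54 kg"}
  biomass: {value: 4.3e+8, low: 4.1e+8, high: 4.5e+8, units: t,
            provenance: "synthesis Results, 0.43 +/- 0.02 Gt"}
  movement_total: {value: 4000, low: 3400, high: 7000, units: Gt km yr-1,
                   provenance: "synthesis Results + Fig. 1c"}
  daily_distance_km: {value: 30, units: km d-1, provenance: "synthesis Results, ~30 km d-1"}
  walking: {value: 600, low: 400, high: 700, units: Gt km yr-1,
            provenance: "synthesis Results, walking"}
  air: {value: 500, low: 400, high: 700, units: Gt km yr-1,
        provenance: "synthesis Results, airplanes"}
  fold_change_since_1850: {value: 40, units: fold,
                           provenance: "synthesis Results + Fig. 3"}
  mode_shares_pct:
    road: {value: 65, provenance: "synthesis Fig. 3, cars and motorcycles"}
    walk_cycle: {value: 20, provenance: "synthesis Fig. 3, walking and cycling"}
    air: {value: 10, provenance: "synthesis Fig. 3, flying"}
    rail: {value: 5, provenance: "synthesis Fig. 3, rail"}
marine:
  movement_1850: {value: 80000, units: Gt km yr-1, provenance: "synthesis Fig. 3, 1850"}
  movement_present: {value: 30000, units: Gt km yr-1, provenance: "synthesis Fig. 3, present"}
  composition_pct:
    pelagic_fish: {value: 70, provenance: "synthesis Fig. 3 doughnut"}
    mesopelagic_fish: {value: 15, provenance: "synthesis Fig. 3 doughnut"}
    zooplankton: {value: 10, provenance: "synthesis Fig. 3 doughnut"}
    marine_mammals: {value: 5, provenance: "synthesis Fig. 3 doughnut"}
energy_table:
  - {group: wild_land_mammals, movement_gt_km_yr: 30, cot_avg: 3,
     printed_energy_twh_yr: 20, printed_power_gw: 2,
     analogue_label: "A large power station",
     provenance: "synthesis Table 1"}
  - {group: wild_birds, movement_gt_km_yr: 30, cot_avg: 9,
     printed_energy_twh_yr: 80, printed_power_gw: 9,
     analogue_label: "Fleet of a major airline carrier",
     provenance: "synthesis Table 1"}
  - {group: marine_mammals, movement_gt_km_yr: 1000, cot_avg: 0.8,
     printed_energy_twh_yr: 200, printed_power_gw: 20,
     analogue_label: "All ships transporting natural gas and chemicals",
     provenance: "synthesis Table 1"}
  - {group: fish, movement_gt_km_yr: 30000, cot_avg: 4,
     printed_energy_twh_yr: 30000, printed_power_gw: 4000,
     analogue_label: "All of human transportation",
     provenance: "synthesis Table 1"}
  - {group: humans_walking, movement_gt_km_yr: 600, cot_avg: 3,
     printed_energy_twh_yr: 500, printed_power_gw: 50,
     analogue_label: "One-tenth of global caloric intake by humans",
     provenance: "synthesis Table 1"}
  - {group: humans_all_transport, movement_gt_km_yr: 4000, cot_avg: 30,
     printed_energy_twh_yr: 30000, printed_power_gw: 4000,
     analogue_label: "One-third of humanity's final energy use",
     provenance: "synthesis Table 1"}
case_studies:
  arctic_terns:
    population: 2.0e+6
    body_mass_kg: 0.1
    annual_distance_km: 8.0e+4
    printed_movement_t_km_yr: 1.6e+7
    provenance: "synthesis Fig. 2, pole-to-pole tern migration"
  grey_wolves:
    movement_gt_km_yr: 0.03
    provenance: "synthesis Fig. 2, global grey wolves"
  serengeti_migration:
    wolves_multiple: 20
    provenance: "synthesis Results, ~20x grey wolves"
  hajj:
    population: 2.0e+6
    provenance: "synthesis Results, ~2 million pilgrims"
  world_cup:
    population: 1.0e+6
    provenance: "synthesis Results, ~1 million spectators"
  humpback_whales:
    population: 8.0e+4
    body_mass_kg: 3.0e+4
    annual_distance_km: 1.5e+4
    provenance: "synthesis Results, ~80,000 mature whales of ~30 t; distance at the described migration scale (synthetic calibration)"
  germany_domestic:
    population: 8.0e+7
    body_mass_kg: 54
    annual_distance_km: 1.5e+4
    provenance: "synthesis Results, ~80 million people at ~15,000 km yr-1"
  diel_vertical_migration:
    biomass_t: 5.0e+9
    daily_distance_km: 1
    printed_daily_gt_km: 4
    printed_annual_gt_km_yr: 1000
    provenance: "synthesis Results, zooplankton + mesopelagic fish"
  bacteria_bound:
    biomass_t: 2.0e+11
    speed_km_h: 3.6e-5
    activity_hours_per_day: 24
    printed_bound_gt_km_yr: 50
    provenance: "synthesis Results, prokaryote order-of-magnitude bound (computes to ~63)"
  passenger_vehicles:
    fleet_mass_gt: 2
    movement_gt_km_yr: 40000
    provenance: "synthesis Results, ~1.3 billion cars"
  food_miles:
    movement_gt_km_yr: 8000
    provenance: "synthesis Results, food transport"
  maritime_trade:
    movement_gt_km_yr: 100000
    provenance: "synthesis Results, international maritime freight (lower bound)"
cot:
  walker_j_kg_m: {value: 3, units: J kg-1 m-1,
                  provenance: "synthesis Results, comfortable adult walk"}
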