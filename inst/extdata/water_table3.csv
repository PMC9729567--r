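location,site,source_description,d2H,d18O,provenance
Vancouver,1,Mixed Capilano/Seymour,-89.0,-11.7,tap
Burnaby,1,Capilano/Seymour,-89.0,-11.1,tap
Surrey,1,Seymour/Coquitlam,-87.3,-11.3,tap
Port Moody,1,Coquitlam,-86.2,-11.1,tap
Coquitlam,1,Coquitlam,-86.2,-11.1,tap
New Westminster,1,Seymour/Coquitlam,-86.8,-11.2,tap
Richmond,1,Capilano/Seymour,-88.1,-11.6,tap
Orillia,2,Lake Couchiching plus two groundwater wells,-64.2,-9.0,surface
Barrie,2,Kempenfelt Bay,-82.2,-12.0,tap
Horseshoe Valley,2,Groundwater,-77.0,-11.1,OIPC
Washago,2,Lake Couchiching,-64.2,-9.0,surface
Lafontaine,2,Groundwater (Severn Sound watershed),-77.0,-11.1,OIPC
Gravenhurst,2,Lake Muskoka,-69.7,-9.5,surface
Midland,2,Groundwater (Severn Sound watershed),-76.0,-11.1,OIPC
Iqaluit,3,Lake Geraldine,-129.0,-17.3,OIPC
Wolfville,4,Groundwater (Cornwallis watershed),-61.8,-9.4,tap
Kentville,4,Groundwater (Cornwallis watershed),-61.8,-9.4,tap
Berwick,4,Groundwater wells (Cornwallis watershed),-61.8,-9.4,tap
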