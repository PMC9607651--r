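{"subject_id":"EX01","operator_id":"demo","repetition":1,"calibration":{"spacing_x_mm":0.2,"spacing_y_mm":0.2,"width_px":512,"height_px":1024},"boundaries":[{"label":"T12-L1","p0":[5,20],"p1":[47,20]},{"label":"L1-L2","p0":[5,45],"p1":[47,45]},{"label":"L2-L3","p0":[5,70],"p1":[47,70]},{"label":"L3-L4","p0":[5,95],"p1":[47,95]},{"label":"L4-L5","p0":[5,120],"p1":[47,120]}],"walls":[{"wall":"anterior","points":[[17.4019237886467,10],[17.5729490168752,11],[17.7705655235678,12],[17.9926081809234,13],[18.2366442431226,14],[18.5,15],[18.7797900707726,16],[19.0729490168752,17],[19.3762649275467,18],[19.686414610197,19],[20,20],[20.313585389803,21],[20.6237350724533,22],[20.9270509831248,23],[21.2202099292274,24],[21.5,25],[21.7633557568774,26],[22.0073918190766,27],[22.2294344764322,28],[22.4270509831248,29],[22.5980762113533,30],[22.7406363729278,31],[22.8531695488855,32],[22.9344428022014,33],[22.9835656861048,34],[23,35],[22.9835656861048,36],[22.9344428022014,37],[22.8531695488855,38],[22.7406363729278,39],[22.5980762113533,40],[22.4270509831248,41],[22.2294344764322,42],[22.0073918190766,43],[21.7633557568774,44],[21.5,45],[21.2202099292274,46],[20.9270509831248,47],[20.6237350724533,48],[20.313585389803,49],[20,50],[19.686414610197,51],[19.3762649275467,52],[19.0729490168752,53],[18.7797900707726,54],[18.5,55],[18.2366442431226,56],[17.9926081809234,57],[17.7705655235678,58],[17.5729490168752,59],[17.4019237886467,60],[17.2593636270722,61],[17.1468304511145,62],[17.0655571977986,63],[17.0164343138952,64],[17,65],[17.0164343138952,66],[17.0655571977986,67],[17.1468304511145,68],[17.2593636270722,69],[17.4019237886467,70],[17.5729490168752,71],[17.7705655235678,72],[17.9926081809234,73],[18.2366442431226,74],[18.5,75],[18.7797900707726,76],[19.0729490168752,77],[19.3762649275467,78],[19.686414610197,79],[20,80],[20.313585389803,81],[20.6237350724533,82],[20.9270509831248,83],[21.2202099292274,84],[21.5,85],[21.7633557568774,86],[22.0073918190766,87],[22.2294344764322,88],[22.4270509831248,89],[22.5980762113533,90],[22.7406363729278,91],[22.8531695488855,92],[22.9344428022014,93],[22.9835656861048,94],[23,95],[22.9835656861048,96],[22.9344428022014,97],[22.8531695488855,98],[22.7406363729278,99],[22.5980762113533,100],[22.4270509831248,101],[22.2294344764322,102],[22.0073918190766,103],[21.7633557568774,104],[21.5,105],[21.2202099292274,106],[20.9270509831248,107],[20.6237350724533,108],[20.313585389803,109],[20,110],[19.686414610197,111],[19.3762649275467,112],[19.0729490168752,113],[18.7797900707726,114],[18.5,115],[18.2366442431226,116],[17.9926081809234,117],[17.7705655235678,118],[17.5729490168752,119],[17.4019237886467,120],[17.2593636270722,121],[17.1468304511145,122],[17.0655571977986,123],[17.0164343138952,124],[17,125],[17.0164343138952,126],[17.0655571977986,127],[17.1468304511145,128],[17.2593636270722,129],[17.4019237886467,130]]},{"wall":"posterior","points":[[29.4019237886467,10],[29.5729490168752,11],[29.7705655235678,12],[29.9926081809234,13],[30.2366442431226,14],[30.5,15],[30.7797900707726,16],[31.0729490168752,17],[31.3762649275467,18],[31.686414610197,19],[32,20],[32.313585389803,21],[32.6237350724533,22],[32.9270509831248,23],[33.2202099292274,24],[33.5,25],[33.7633557568774,26],[34.0073918190766,27],[34.2294344764322,28],[34.4270509831248,29],[34.5980762113533,30],[34.7406363729278,31],[34.8531695488855,32],[34.9344428022014,33],[34.9835656861048,34],[35,35],[34.9835656861048,36],[34.9344428022014,37],[34.8531695488855,38],[34.7406363729278,39],[34.5980762113533,40],[34.4270509831248,41],[34.2294344764322,42],[34.0073918190766,43],[33.7633557568774,44],[33.5,45],[33.2202099292274,46],[32.9270509831248,47],[32.6237350724533,48],[32.313585389803,49],[32,50],[31.686414610197,51],[31.3762649275467,52],[31.0729490168752,53],[30.7797900707726,54],[30.5,55],[30.2366442431226,56],[29.9926081809234,57],[29.7705655235678,58],[29.5729490168752,59],[29.4019237886467,60],[29.2593636270722,61],[29.1468304511145,62],[29.0655571977986,63],[29.0164343138952,64],[29,65],[29.0164343138952,66],[29.0655571977986,67],[29.1468304511145,68],[29.2593636270722,69],[29.4019237886467,70],[29.5729490168752,71],[29.7705655235678,72],[29.9926081809234,73],[30.2366442431226,74],[30.5,75],[30.7797900707726,76],[31.0729490168752,77],[31.3762649275467,78],[31.686414610197,79],[32,80],[32.313585389803,81],[32.6237350724533,82],[32.9270509831248,83],[33.2202099292274,84],[33.5,85],[33.7633557568774,86],[34.0073918190766,87],[34.2294344764322,88],[34.4270509831248,89],[34.5980762113533,90],[34.7406363729278,91],[34.8531695488855,92],[34.9344428022014,93],[34.9835656861048,94],[35,95],[34.9835656861048,96],[34.9344428022014,97],[34.8531695488855,98],[34.7406363729278,99],[34.5980762113533,100],[34.4270509831248,101],[34.2294344764322,102],[34.0073918190766,103],[33.7633557568774,104],[33.5,105],[33.2202099292274,106],[32.9270509831248,107],[32.6237350724533,108],[32.313585389803,109],[32,110],[31.686414610197,111],[31.3762649275467,112],[31.0729490168752,113],[30.7797900707726,114],[30.5,115],[30.2366442431226,116],[29.9926081809234,117],[29.7705655235678,118],[29.5729490168752,119],[29.4019237886467,120],[29.2593636270722,121],[29.1468304511145,122],[29.0655571977986,123],[29.0164343138952,124],[29,125],[29.0164343138952,126],[29.0655571977986,127],[29.1468304511145,128],[29.2593636270722,129],[29.4019237886467,130]]}],"tracts":[{"wall":"anterior","points":[[22.70731343451,39.2337464972665],[22.5980762113533,40],[22.4270509831248,41],[22.2294344764322,42],[22.0073918190766,43],[21.7633557568774,44],[21.5446349649358,44.8305145652973]]},{"wall":"anterior","points":[[18.2792606428829,55.8381793499955],[18.2366442431226,56],[17.9926081809234,57],[17.7705655235678,58],[17.5729490168752,59],[17.4019237886467,60],[17.2593636270722,61],[17.1468304511145,62],[17.0655571977986,63],[17.0164343138952,64],[17,65],[17.0164343138952,66],[17.0655571977986,67],[17.1468304511145,68],[17.2252704950572,68.6970392799735]]},{"wall":"anterior","points":[[22.1728899114768,87.7453436847282],[22.2294344764322,88],[22.4270509831248,89],[22.5980762113533,90],[22.7406363729278,91],[22.8531695488855,92],[22.9344428022014,93],[22.9835656861048,94],[23,95],[22.9835656861048,96],[22.9344428022014,97],[22.8788375528376,97.6841764922053]]},{"wall":"posterior","points":[[34.7726333171376,31.2843334326741],[34.8531695488855,32],[34.9344428022014,33],[34.9835656861048,34],[35,35],[34.9835656861048,36],[34.9344428022014,37],[34.8531695488855,38],[34.7406363729278,39],[34.5980762113533,40],[34.4270509831248,41],[34.2294344764322,42],[34.0073918190766,43],[33.7633557568774,44],[33.5,45],[33.2202099292274,46],[32.9270509831248,47],[32.6237350724533,48],[32.313585389803,49],[32.2073071912189,49.3389131064137]]},{"wall":"posterior","points":[[34.7494429434908,91.0782575492787],[34.8531695488855,92],[34.9344428022014,93],[34.9835656861048,94],[35,95],[34.9835656861048,96],[34.9344428022014,97],[34.8531695488855,98],[34.7406363729278,99],[34.5980762113533,100],[34.4270509831248,101],[34.3605533878527,101.336498182187]]}],"sv_score":10}
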