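"band","rho","aec"
"delta",0,-0.0206341939937444
"delta",0.05,-0.0173762120853291
"delta",0.1,0.00796685442340682
"delta",0.15,0.00796685442340682
"delta",0.2,0.00796685442340682
"delta",0.25,0.0384481007239385
"delta",0.3,0.0384481007239385
"delta",0.35,0.0545945508487872
"delta",0.4,0.0825044588487941
"delta",0.45,0.0825044588487941
"delta",0.5,0.109819149867432
"delta",0.55,0.109819149867432
"delta",0.6,0.109819149867432
"delta",0.65,0.191761664501407
"delta",0.7,0.196232530197412
"delta",0.75,0.236349713434028
"delta",0.8,0.27741167221915
"delta",0.85,0.303836660654203
"delta",0.9,0.339908248471518
"delta",0.95,0.408063858294386
"theta",0,-0.00821718044558016
"theta",0.05,0.0122837901505276
"theta",0.1,0.0192559978010199
"theta",0.15,0.0192559978010199
"theta",0.2,0.0192559978010199
"theta",0.25,0.0192559978010199
"theta",0.3,0.0549959482809076
"theta",0.35,0.0611215780853897
"theta",0.4,0.10574729303231
"theta",0.45,0.116874057948921
"theta",0.5,0.116874057948921
"theta",0.55,0.169679502770616
"theta",0.6,0.18518091621403
"theta",0.65,0.18518091621403
"theta",0.7,0.18518091621403
"theta",0.75,0.295741342265104
"theta",0.8,0.337247994692706
"theta",0.85,0.362976011031758
"theta",0.9,0.427032171136376
"theta",0.95,0.475942632185783
"alpha",0,0.00990796493175082
"alpha",0.05,0.00990796493175082
"alpha",0.1,0.00990796493175082
"alpha",0.15,0.00990796493175082
"alpha",0.2,0.00990796493175082
"alpha",0.25,0.088172800167418
"alpha",0.3,0.088172800167418
"alpha",0.35,0.0919813291190438
"alpha",0.4,0.0919813291190438
"alpha",0.45,0.117670923214406
"alpha",0.5,0.134595694438379
"alpha",0.55,0.134595694438379
"alpha",0.6,0.213690696549547
"alpha",0.65,0.253122460183584
"alpha",0.7,0.253122460183584
"alpha",0.75,0.316385986488929
"alpha",0.8,0.353223365746029
"alpha",0.85,0.464538737632235
"alpha",0.9,0.517471344823068
"alpha",0.95,0.58564129628449
"beta",0,-0.0281020039952686
"beta",0.05,0.0024431183271905
"beta",0.1,0.0024431183271905
"beta",0.15,0.0107445484767458
"beta",0.2,0.0107445484767458
"beta",0.25,0.0380823272048041
"beta",0.3,0.0507383021732649
"beta",0.35,0.0623431910555408
"beta",0.4,0.120154244642459
"beta",0.45,0.152719799440396
"beta",0.5,0.155323853310472
"beta",0.55,0.221291118832076
"beta",0.6,0.255324209015146
"beta",0.65,0.292382029241081
"beta",0.7,0.34338083255937
"beta",0.75,0.373035770451539
"beta",0.8,0.453418248291023
"beta",0.85,0.531160446655274
"beta",0.9,0.624654326253662
"beta",0.95,0.70843903399745
"lgamma1",0,0.0204148402941562
"lgamma1",0.05,0.0204148402941562
"lgamma1",0.1,0.0204148402941562
"lgamma1",0.15,0.0204148402941562
"lgamma1",0.2,0.0204148402941562
"lgamma1",0.25,0.0746599403470733
"lgamma1",0.3,0.082532091684601
"lgamma1",0.35,0.101826460241826
"lgamma1",0.4,0.106583211106239
"lgamma1",0.45,0.157845879205246
"lgamma1",0.5,0.165746997777491
"lgamma1",0.55,0.217403952389001
"lgamma1",0.6,0.242882219391077
"lgamma1",0.65,0.330831704501137
"lgamma1",0.7,0.383980313734427
"lgamma1",0.75,0.403991480965465
"lgamma1",0.8,0.506534692633884
"lgamma1",0.85,0.555260086829283
"lgamma1",0.9,0.667162020999228
"lgamma1",0.95,0.786023248993922
"lgamma2",0,-0.0255650383752534
"lgamma2",0.05,-0.0113199527112904
"lgamma2",0.1,-0.00652253699060749
"lgamma2",0.15,-0.00652253699060749
"lgamma2",0.2,0.0439499310034528
"lgamma2",0.25,0.0439499310034528
"lgamma2",0.3,0.0563145796365722
"lgamma2",0.35,0.0834385165589324
"lgamma2",0.4,0.0834385165589324
"lgamma2",0.45,0.120753801486927
"lgamma2",0.5,0.175885514929597
"lgamma2",0.55,0.175885514929597
"lgamma2",0.6,0.261374889800023
"lgamma2",0.65,0.261374889800023
"lgamma2",0.7,0.331002387921129
"lgamma2",0.75,0.411961886407258
"lgamma2",0.8,0.477063533657811
"lgamma2",0.85,0.566013498749168
"lgamma2",0.9,0.652325523832072
"lgamma2",0.95,0.738225030570157
"hgamma",0,-0.0270222753984785
"hgamma",0.05,0.00355543276676404
"hgamma",0.1,0.022339010535736
"hgamma",0.15,0.0273701288826363
"hgamma",0.2,0.0273701288826363
"hgamma",0.25,0.0273701288826363
"hgamma",0.3,0.0794811222410568
"hgamma",0.35,0.109865203001652
"hgamma",0.4,0.128888291856103
"hgamma",0.45,0.137097131970783
"hgamma",0.5,0.175634012716824
"hgamma",0.55,0.21498025154241
"hgamma",0.6,0.293663907822438
"hgamma",0.65,0.338272904098126
"hgamma",0.7,0.358436386806587
"hgamma",0.75,0.451300466434853
"hgamma",0.8,0.52472324114259
"hgamma",0.85,0.613287082667845
"hgamma",0.9,0.727276247449776
"hgamma",0.95,0.825700451704488
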