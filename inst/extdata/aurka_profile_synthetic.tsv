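position	aa	motif	anchor
127	F		
128	L		
129	S		
130	F		
131	S		
132	E		
133	M		
134	E		
135	A		
136	G	G-loop	
137	R	G-loop	
138	P	G-loop	
139	L	G-loop	L139
140	A	G-loop	
141	K	G-loop	K141
142	G	G-loop	G142
143	K	G-loop	K143
144	F	G-loop	F144
145	G	G-loop	G145
146	K	G-loop	
147	F	G-loop	
148	Y	G-loop	
149	I		
150	W		
151	M		
152	S		
153	L		
154	F		
155	F		
156	L		
157	K		
158	P		
159	S		
160	K		
161	T		
162	K		K162
163	L		
164	A		
165	F		
166	K		
167	S		
168	P		
169	I		
170	A		
171	T		
172	D		
173	L	alphaC	
174	G	alphaC	
175	E	alphaC	
176	H	alphaC	
177	Q	alphaC	Q177
178	L	alphaC	
179	R	alphaC	
180	R	alphaC	R180
181	E	alphaC	E181
182	I	alphaC	
183	E	alphaC	
184	P	alphaC	
185	Q	alphaC	Q185
186	P	alphaC	
187	A	alphaC	
188	M	alphaC	
189	R	alphaC	
190	W		
191	H		
192	A		
193	A		
194	L		
195	R		
196	T		
197	Y		
198	L		
199	Y		
200	F		
201	Y		
202	C		
203	V		
204	Q		
205	R		
206	A		
207	Y		
208	Y		
209	A		
210	L	hinge	GK
211	E	hinge	GK+1
212	Y	hinge	GK+2
213	A	hinge	GK+3
214	P	hinge	GK+4
215	L	hinge	GK+5
216	G	hinge	GK+6
217	T	hinge	GK+7
218	V		
219	Y		
220	R		GK+10
221	C		
222	G		
223	Q		
224	K		
225	T		
226	T		
227	D		
228	L		
229	W		
230	E		
231	V		
232	M		
233	L		
234	M		
235	R		
236	Q		
237	I		
238	A		
239	T		
240	T		
241	S		
242	D		
243	S		
244	S		
245	S		
246	Y		
247	F		
248	P		
249	Q		
250	V		
251	Q		
252	G		
253	I		
254	H		H254
255	R		R255
256	D		
257	D		
258	H		
259	T		
260	E		
261	S		
262	V		
263	I		
264	S		
265	M		
266	L		
267	P		
268	L		
269	A		
270	T		
271	K		
272	P		
273	A		A273
274	D	DFG	D274
275	F	DFG	F275
276	G	DFG	G276
277	W	A-loop	W277
278	D	A-loop	
279	V	A-loop	V279
280	H	A-loop	H280
281	S	A-loop	
282	D	A-loop	
283	D	A-loop	
284	S	A-loop	
285	R	A-loop	
286	T	A-loop	
287	T	A-loop	
288	T	A-loop	T288
289	Q		
290	V		
291	N		
292	S		
293	S		
294	S		
295	R		
296	G		
297	M		
298	V		
299	S		
300	N		
301	T		
302	Q		
303	L		
304	A		
305	H		
306	H		
307	G		
308	Y		
309	L		
310	P		
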